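# Reference frame for Escherichia coli K-12 MG1655, assembly NC_000913.3.
# 0-based coordinates; terminus window brackets the dif site.
length = 4641652
oric = 3925744
terminus_start = 1507157
terminus_end = 1707157
# head-on rRNA collision locus (inverted rrnD operon)
invD = 3427221
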