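; CSB 2 anchor configuration: flanks of the variable G-tract (rCRS 303-315)
>upstream_flank rCRS:294-302 strand=reference
TCCACCAAA
>downstream_flank rCRS:316-325 strand=reference
GCTTCTGGCC
>upstream_context rCRS:241-293 strand=reference
ACAATTGAATGTCTGCACAGCCGCTTTCCACACAGACATCATAACAAAAAATT
>downstream_context rCRS:326-400 strand=reference
ACAGCACTTAAACACATCTCTGCCAAACCCCAAAAACAAAGAACCCTAACACCAGCCTAACCAGATTTCAAAAAA
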