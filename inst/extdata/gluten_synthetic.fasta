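>wheat_gliadin_synthetic
MASRWQIPEQSRRAQIPQQLRVQGQGIIQPQQPAQLRPYSQPQPFRPQQTFPQQPLFRPQ
PPQQPFRQEQQIGQEQQPGQWRPQQSEQVIPQQPQQPFRQQQPPFWQQQPPFRRPQQPYP
QPQPQYRWQTPEQSRRVYYPTSPQQPGQLRPQPQPFPQQL
>rye_secalin_synthetic
MASRIVQGQSIIQQQPAQLRAQVQGIIQPQQLRQPQQPFPQQPQQSFRQIPTPLQPQQPF
RAQIPQHLRPQPQPFPQQL
>barley_hordein_synthetic
MASRQGQQGQQLGQGQQGYYRVQQQQPPFRPQQPGQWRIIPQQPQQPFPLQPHQPYRPQQ
PGQGQQPGQRRPQQPGQGQGQQGYYPGATSLRPLQPQQPFPWRPQQQFPQQQFHQQQLRF
PQYQIPTPLRPQPQPFPQQL
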