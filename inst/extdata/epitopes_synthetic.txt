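# Synthetic stand-in epitope list (NOT the published immunogenic peptide
# set): proline/glutamine-rich peptides with the length spectrum of
# celiac-disease T-cell epitopes (11, 12, 13, 16 and 20 residues),
# generated for pipeline demonstrations and negative-control scans.
QPQQPFPQQAY
PQQLFPQQQPF
QQPFPQQAYPQS
PFPQPQQPTPIQ
QLQPQNPSQQQPQ
PQPQQQFPQTQQP
QQPQQPFPQPQQTFPHQP
QPQQTYPQRPQQPFPQ
LQPQNPSQQQPQEQVPLVQQ
QQPQQPYPQQQPQYLQPQQP
FPQQQLPLQPQQPFPQQPQQ
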