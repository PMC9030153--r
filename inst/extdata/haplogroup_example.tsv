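variant	frequency
A10262G	1.95
C960CC	2.66
C150T	85.2
T152C	61.7
A12308G	99.69
G12372A	97.4
C16192T	44.1
C16270T	90.3
A11467G	98.9
A13637G	1.33
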