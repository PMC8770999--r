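*HEADING
unsupported element type fixture
*NODE
1, 0.0, 0.0, 0.0
2, 1.0, 0.0, 0.0
3, 0.0, 1.0, 0.0
4, 1.0, 1.0, 0.0
*ELEMENT, TYPE=S4, ELSET=shell
1, 1, 2, 4, 3
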