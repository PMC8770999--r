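*HEADING
single regular tetrahedron fixture
*NODE
1, 0.0, 0.0, 0.0
2, 1.0, 0.0, 0.0
3, 0.0, 1.0, 0.0
4, 0.0, 0.0, 1.0
*ELEMENT, TYPE=C3D4, ELSET=solid
1, 1, 2, 3, 4
*NSET, NSET=base
1, 2, 3
*NSET, NSET=apex
4
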