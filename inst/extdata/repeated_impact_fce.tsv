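mirna	fce_hfc	padj_hfc	fce_hfhf	padj_hfhf
miR-323-3p	0.5	1.1E-02	0.4	5.3E-03
miR-323-5p	0.5	6.5E-03	0.7	5.3E-03
miR-3585-3p	3.4	3.1E-02	3.2	2.4E-02
miR-3585-5p	4.8	9.3E-03	4.6	2.3E-02
miR-433-3p	0.6	1.0E-02	0.6	2.0E-03
miR-433-5p	0.6	4.7E-02	0.5	1.7E-02
miR-485-3p	0.6	1.8E-03	0.5	5.1E-04
miR-485-5p	0.8	4.2E-02	0.8	2.2E-02
miR-543-3p	0.8	6.9E-03	0.5	1.7E-05
miR-543-5p	0.6	2.2E-02	1.0	4.2E-01
miR-547-3p	3.3	5.0E-02	3.6	5.2E-02
miR-770-3p	0.6	1.0E-02	0.5	5.3E-03
miR-770-5p	0.6	1.2E-02	0.7	1.1E-02
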