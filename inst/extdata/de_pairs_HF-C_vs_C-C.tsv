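mirna	fce	padj	partner	partner_fce	partner_padj
let-7i-5p	1.9	6.5E-03	let-7i-3p	1.5	3.1E-01
miR-107-3p	0.6	9.3E-03	NA	NA	NA
miR-1188-5p	0.4	7.0E-03	NA	NA	NA
miR-132-3p	1.7	5.1E-03	miR-132-5p	1.3	2.5E-01
miR-140-5p	1.7	6.5E-03	miR-140-3p	0.9	1.9E-01
miR-28-5p	1.7	6.9E-03	miR-28-3p	0.8	9.3E-02
miR-221-5p	1.9	1.0E-02	miR-221-3p	1.6	6.2E-02
miR-323-5p	0.5	6.5E-03	miR-323-3p	0.5	1.1E-02
miR-338-5p	1.5	4.2E-03	miR-338-3p	1.4	3.1E-01
miR-3585-5p	4.8	9.3E-03	miR-3585-3p	3.4	3.1E-02
miR-433-3p	0.6	1.0E-02	miR-433-5p	0.6	4.7E-02
miR-485-3p	0.6	1.8E-03	miR-485-5p	0.8	4.2E-02
miR-543-3p	0.8	6.9E-03	miR-543-5p	0.6	2.2E-02
miR-668	0.6	9.3E-03	NA	NA	NA
miR-673-5p	0.5	6.5E-03	NA	NA	NA
miR-708-5p	1.6	7.7E-04	miR-708-3p	0.9	3.4E-01
miR-770-3p	0.6	1.0E-02	miR-770-5p	0.6	1.2E-02
miR-92a-3p	0.8	1.8E-03	NA	NA	NA
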