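mirna	fce	padj	partner	partner_fce	partner_padj
let-7a-1-3p	1.9	4.0E-03	let-7a-5p	0.7	6.5E-02
let-7i-5p	1.6	6.4E-03	let-7i-3p	1.4	5.6E-02
miR-1188-5p	0.4	5.7E-03	NA	NA	NA
miR-1224	0.5	5.1E-03	NA	NA	NA
miR-127-3p	0.7	9.2E-03	miR-127-5p	0.7	2.3E-02
miR-132-3p	1.9	6.6E-03	miR-132-5p	1.1	2.8E-01
miR-134-3p	1.8	8.1E-03	miR-134-5p	0.9	6.3E-02
miR-139-3p	0.6	5.7E-03	miR-139-5p	0.7	2.3E-02
miR-140-5p	2.1	3.0E-04	miR-140-3p	1.1	3.3E-02
miR-145-5p	3.4	8.1E-03	miR-145-3p	2.1	1.8E-02
miR-149-5p	0.6	5.1E-03	NA	NA	NA
miR-153-3p	1.9	9.7E-03	miR-153-5p	1.2	1.8E-01
miR-154-5p	1.5	4.9E-03	miR-154-3p	0.8	6.5E-02
miR-1843b-3p	0.6	9.1E-03	NA	NA	NA
miR-185-5p	1.5	4.5E-03	NA	NA	NA
miR-192-5p	1.7	2.9E-03	NA	NA	NA
miR-212-3p	1.9	3.1E-03	miR-212-5p	1.3	5.1E-02
miR-23a-3p	2.0	3.0E-03	miR-23a-5p	0.8	2.1E-01
miR-25-3p	1.6	5.7E-03	miR-25-5p	0.7	1.5E-02
miR-27a-3p	2.1	1.0E-02	miR-27a-5p	2.6	2.7E-02
miR-27b-3p	1.8	5.7E-03	miR-27b-5p	1.4	8.1E-02
miR-28-5p	1.7	5.1E-03	miR-28-3p	0.9	3.3E-01
miR-298-3p	0.4	2.0E-02	miR-298-5p	1.1	2.7E-01
miR-29a-3p	1.6	9.7E-03	miR-29a-5p	1.7	2.1E-02
miR-3068-5p	1.8	8.1E-04	miR-3068-3p	1.0	4.8E-01
miR-329-3p	0.7	9.7E-03	miR-329-5p	1.0	4.8E-01
miR-335	1.5	2.0E-03	NA	NA	NA
miR-344b-1-3p	0.5	9.7E-03	miR-344b-5p	0.7	2.1E-02
miR-34a-5p	2.1	2.9E-02	NA	NA	NA
miR-34c-5p	1.9	2.9E-03	miR-34c-3p	1.2	2.2E-01
miR-369-5p	0.8	5.3E-03	miR-369-3p	0.7	4.4E-02
miR-376b-3p	0.6	9.7E-03	miR-376b-5p	1.0	4.4E-01
miR-376c-3p	1.8	7.0E-04	NA	NA	NA
miR-409a-5p	0.6	9.9E-03	miR-409a-3p	0.7	2.5E-02
miR-410-3p	0.5	9.5E-03	NA	NA	NA
miR-434-3p	0.7	9.7E-03	miR-434-5p	1.3	5.9E-02
miR-487b-3p	0.6	5.3E-03	NA	NA	NA
miR-493-5p	0.6	9.7E-03	miR-493-3p	1.8	1.7E-02
miR-495	0.6	2.0E-03	NA	NA	NA
miR-504	0.6	6.7E-04	NA	NA	NA
miR-505-5p	0.7	1.0E-02	miR-505-3p	1.2	4.0E-02
miR-539-3p	2.2	7.7E-03	miR-539-5p	0.9	1.5E-01
miR-652-5p	1.9	7.8E-03	miR-652-3p	1.1	2.6E-01
miR-668	0.6	5.8E-03	NA	NA	NA
miR-708-5p	1.6	3.6E-04	miR-708-3p	0.9	3.1E-01
miR-760-3p	0.5	2.9E-03	NA	NA	NA
miR-7a-1-3p	1.7	8.1E-03	miR-7a-5p	1.2	2.0E-01
miR-7a-2-3p	1.7	1.0E-02	miR-7a-5p	1.2	2.0E-01
miR-872-5p	1.6	9.7E-03	miR-872-3p	1.1	2.7E-01
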