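chrom	start	end	n_snps	length	type	sample	start_snp	end_snp	relationship
chr1	193577075	193861997	44	284923	del	10	rs1359381	rs12745696	Offspring
chr1	193577075	193861997	44	284923	del	4	rs1359381	rs12745696	Offspring
chr1	193577075	193861997	44	284923	del	2	rs1359381	rs12745696	Father
chr13	26048387	26099109	10	50723	dup	7	rs2133814	rs7986966	Offspring
chr13	26048387	26099109	10	50723	dup	10	rs2133814	rs7986966	Offspring
chr13	26048387	26099109	10	50723	dup	6	rs2133814	rs7986966	Offspring
chr13	26048387	26099109	10	50723	dup	8	rs2133814	rs7986966	Offspring
chr13	26048387	26099109	10	50723	dup	1	rs2133814	rs7986966	Mother
chr2	41082092	41099005	11	16914	del	6	rs12474136	rs2373974	Offspring
chr2	41082092	41099005	11	16914	del	8	rs12474136	rs2373974	Offspring
chr2	41082092	41099005	11	16914	del	3	rs12474136	rs2373974	Offspring
chr2	41082092	41099005	11	16914	del	2	rs12474136	rs2373974	Father
chr8	3753745	3763223	14	9479	del	5	rs2930372	rs1464619	Offspring
chr8	3753745	3763223	14	9479	del	7	rs2930372	rs1464619	Offspring
chr8	3753745	3763223	14	9479	del	4	rs2930372	rs1464619	Offspring
chr8	3753745	3763223	14	9479	del	6	rs2930372	rs1464619	Offspring
chr8	3753745	3763223	14	9479	del	8	rs2930372	rs1464619	Offspring
chr8	3753745	3763223	14	9479	del	3	rs2930372	rs1464619	Offspring
chr8	3753745	3763223	14	9479	del	1	rs2930372	rs1464619	Mother
chrX	22775615	22833684	14	58070	del	5	rs7889437	rs5970944	Offspring
chrX	22775615	22833684	14	58070	del	7	rs7889437	rs5970944	Offspring
chrX	22775615	22833684	14	58070	del	4	rs7889437	rs5970944	Offspring
chrX	22775615	22833684	14	58070	del	3	rs7889437	rs5970944	Offspring
chrX	22775615	22833684	14	58070	del	2	rs7889437	rs5970944	Father
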