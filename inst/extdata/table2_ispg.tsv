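phylum	species_strain	complement_aerobic	complement_etp	complement_anaerobic	complemented_or_recovered	tir_log10	sds_page	ms_detected	o2_tolerance	temperature_class	fes_system	is_host_control
Acidobacteria	Candidatus Koribacter versatilis Ellin345	-	NT	-	-	3.6	-	detection_NT	+	mesophilic	IscU	FALSE
Actinobacteria	Thermoleophilum album	-	NT	-	-	2.9	-	detection_NT	+	thermophilic	SufBD	FALSE
Actinobacteria	Streptomyces coelicolor A3	-	-	-	-	2.6	-	-	+	mesophilic	SufBD	FALSE
Actinobacteria	Rubrobacter xylanophilus DSM 9941	+	NT	+	+	2.6	-	NT	+	thermophilic	SufBD	FALSE
Actinobacteria	Cutibacterium acnes KPA171202	+	NT	+	+	4.7	-	NT	-	mesophilic	SufBD	FALSE
Actinobacteria	Collinsella stercoris DSM 13279	-	-	+	+	3.3	-	-	-	mesophilic	SufBD	FALSE
Actinobacteria	Acidimicrobium ferrooxidans DSM 10331	+	NT	+	+	3.5	-	NT	+	mesophilic	SufBD	FALSE
Actinobacteria	Streptomyces cattleya NRRL 8057 = DSM 46488	-	+	-	+	2.7	+	NT	+	mesophilic	SufBD	FALSE
Actinobacteria	Egibacter sp.	-	NT	-	-	3.4	-	detection_NT	?	?	SufBD	FALSE
Aquificae	Aquifex aeolicus VF5	+	NT	+	+	3.8	-	NT	+	hyperthermophilic	IscU	FALSE
Aquificae	Thermovibrio ammonificans HB-1	-	NT	-	-	2.9	-	detection_NT	-	thermophilic	SufBD	FALSE
Bacteroidetes	Pedobacter heparinus DSM 2366	-	NT	-	-	NT	-	detection_NT	+	mesophilic	SufBD, IscU	FALSE
Bacteroidetes	Salinivirga cyanobacteriivorans	-	NT	-	-	NT	-	detection_NT	-	mesophilic	SufBD	FALSE
Candidatus Fermentibacteria	Candidatus Fermentibacter daniensis	-	NT	-	-	3.0	-	detection_NT	-	mesophilic	IscU	FALSE
Candidatus Melainabacteria	Candidatus Caenarcanum bioreactoricola	-	NT	-	-	4.1	-	detection_NT	?	?	IscU	FALSE
Candidatus Melainabacteria	Candidatus Gastranaerophilales bacterium HUM_7	-	NT	-	-	4.2	-	detection_NT	-	?	IscU	FALSE
Candidatus Sumerlaeota	Candidatus Sumerlaea chitinovorans	-	NT	-	-	2.9	-	detection_NT	?	?	SufBD	FALSE
Chlamydiae	Chlamydia caviae GPIC	-	-	-	-	2.7	-	-	+	mesophilic	SufBD	FALSE
Chloroflexi	Sphaerobacter thermophilus DSM 20745	-	NT	-	-	NT	-	detection_NT	+	thermophilic	SufBD	FALSE
Cyanobacteria	Gloeobacter violaceus PCC 7421	-	-	-	-	3.6	-	detection_NT	+	?	SufBD	FALSE
Cyanobacteria	Synechocystis sp. PCC 6803	-	+	-	+	3.5	-	NT	+	mesophilic	SufBD	FALSE
Deinococcus-Thermus	Thermus thermophilus HB27	-	-	-	-	2.7	-	-	+	thermophilic	SufBD	FALSE
Fibrobacteres	Fibrobacter succinogenes subsp. succinogenes S85	-	NT	-	-	2.6	-	detection_NT	-	mesophilic	SufBD	FALSE
Firmicutes	Bacillus subtilis subsp. subtilis str. 168	-	+	-	+	2.7	-	NT	+	mesophilic	SufBD	FALSE
Firmicutes	Desulfitobacterium hafniense DCB-2	-	-	-	-	3.4	-	+	-	mesophilic	SufBD	FALSE
Firmicutes	Symbiobacterium thermophilum IAM 14863	-	-	-	-	2.0	-	+	+	thermophilic	SufBD	FALSE
Firmicutes	Ruminiclostridium cellulolyticum H10	-	-	-	-	3.4	-	+	-	mesophilic	IscU	FALSE
Lentisphaerae	Victivallales bacterium CCUG 44730	-	NT	-	-	NT	-	detection_NT	?	?	IscU	FALSE
Nitrospinae	Nitrospina gracilis	-	-	-	-	4.0	-	-	+	mesophilic	SufBD	FALSE
Planctomycetes	Blastopirellula marina DSM 3645	partial	+	+	+	3.1	-	NT	+	mesophilic	SufBD	FALSE
Planctomycetes	Isosphaera pallida ATCC 43644	-	-	-	-	2.5	-	+	+	mesophilic	SufBD	FALSE
Planctomycetes	Phycisphaera mikurensis NBRC 102666	-	NT	-	-	3.8	-	detection_NT	+	mesophilic	SufBD	FALSE
Proteobacteria	Aeromonas hydrophila	+	NT	+	+	2.1	-	NT	+	mesophilic	IscU	FALSE
Proteobacteria	Allochromatium vinosum	-	-	-	-	3.7	-	+	-	mesophilic	SufBD, IscU (NifU)	FALSE
Proteobacteria	Azoarcus sp. BH72	+	NT	+	+	3.1	+	NT	-	mesophilic	IscU	FALSE
Proteobacteria	Helicobacter pylori J99	-	-	+	+	3.3	+	+	+	mesophilic	IscU	FALSE
Proteobacteria	Methylococcus capsulatus str. Bath	+	NT	+	+	3.2	-	NT	+	mesophilic	SufBD, IscU	FALSE
Proteobacteria	Rhodobacter sphaeroides 2.4.1	-	+	-	+	3.4	-	NT	+	mesophilic	SufBD, IscU (NifU)	FALSE
Proteobacteria	Mariprofundus ferrooxydans	-	+	-	+	3.7	-	+	+	mesophilic	SufBD	FALSE
Proteobacteria	Cellvibrio japonicus Ueda107	-	-	-	-	2.6	-	-	+	mesophilic	SufBD	FALSE
Proteobacteria	Escherichia coli str. K-12 substr. MG1655	+	NT	+	+	3.1	+	+	+	mesophilic	SufBD, IscU	TRUE
Proteobacteria	Anaplasma phagocytophilum str. CRT38	-	-	-	-	2.2	-	detection_NT	+	?	IscU	FALSE
Spirochaetes	Spirochaeta thermophila DSM 6578	-	-	-	-	4.0	-	+	-	thermophilic	SufBD	FALSE
Synergistetes	Thermanaerovibrio acidaminovorans DSM 6589	-	NT	-	-	3.1	-	detection_NT	-	thermophilic	SufBD, IscU	FALSE
Tenericutes	Spiroplasma citri	-	NT	-	-	3.0	-	detection_NT	+	mesophilic	SufBD	FALSE
Thermodesulfobacteria	Thermodesulfatator indicus DSM 15286	-	NT	-	-	3.3	-	detection_NT	-	thermophilic	SufBD	FALSE
Thermotogae	Thermotoga maritima MSB8	-	-	+	+	4.4	+	+	-	hyperthermophilic	SufBD	FALSE
Verrucomicrobia	Coraliomargarita akajimensis DSM 45221	-	-	-	-	2.6	-	+	+	mesophilic	SufBD	FALSE
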