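phylum	species_strain	complement_aerobic	complement_bssuf	complement_ecsuf	complement_anaerobic	complemented_or_recovered	tir_log10	sds_page	ms_detected	o2_tolerance	temperature_class	fes_system	is_host_control	is_suf_donor
Actinobacteria	Mycolicibacterium smegmatis MC2 155	-	+	+	+	+	3.3	-	+	+	mesophilic	SufBD	FALSE	FALSE
Actinobacteria	Rubrobacter xylanophilus DSM 9941	+	NT	NT	+	+	2.7	-	NT	+	thermophilic	SufBD	FALSE	FALSE
Actinobacteria	Collinsella stercoris DSM 13279	-	-	-	-	-	3.4	-	detection_NT	-	mesophilic	SufBD	FALSE	FALSE
Actinobacteria	Acidimicrobium ferrooxidans DSM 10331	-	+	-	-	+	2.2	-	NT	+	thermophilic	SufBD	FALSE	FALSE
Actinobacteria	Streptomyces cattleya NRRL 8057 = DSM 46488	-	-	-	-	-	4.8	-	+	+	mesophilic	SufBD	FALSE	FALSE
Bacteroidetes	Salinivirga cyanobacteriivorans	+	NT	NT	+	+	NT	+	NT	-	mesophilic	SufBD	FALSE	FALSE
Candidatus Fermentibacteria	Candidatus Fermentibacter daniensis	-	-	-	-	-	3.9	-	detection_NT	-	mesophilic	IscU	FALSE	FALSE
Candidatus Melainabacteria	Candidatus Gastranaerophilales bacterium HUM_7	-	-	-	+	+	3.8	-	NT	-	?	IscU	FALSE	FALSE
Chloroflexi	Sphaerobacter thermophilus DSM 20745	-	+	-	+	+	4.1	-	NT	+	thermophilic	SufBD	FALSE	FALSE
Chloroflexi	Thermogemmatispora tikiterensis	-	-	-	-	-	2.8	-	detection_NT	+	thermophilic	SufBD	FALSE	FALSE
Chrysiogenetes	Desulfurispirillum indicum S5	-	-	-	+	+	3.6	+	NT	-	mesophilic	IscU	FALSE	FALSE
Cyanobacteria	Synechocystis sp. PCC 6803	-	+	-	-	+	3.3	-	NT	+	mesophilic	SufBD	FALSE	FALSE
Cyanobacteria	Crocosphaera watsonii WH 8501	-	+	-	-	+	2.8	-	NT	+	?	SufBD	FALSE	FALSE
Deinococcus-Thermus	Thermus thermophilus HB27	-	+	-	-	+	3.5	-	NT	+	thermophilic	SufBD	FALSE	FALSE
Dictyoglomi	Dictyoglomus thermophilum H-6-12	-	-	-	+	+	3.6	+	NT	-	hyperthermophilic	SufBD, IscU	FALSE	FALSE
Euryarchaeota	Methanopyrus kandleri AV19	-	-	-	-	-	2.9	-	detection_NT	-	hyperthermophilic	SufBD	FALSE	FALSE
Euryarchaeota	Haloferax volcanii DS2	-	-	-	-	-	3.1	-	detection_NT	+	mesophilic	SufBD	FALSE	FALSE
Euryarchaeota	Haloterrigena turkmenica DSM 5511	-	-	-	-	-	3.8	-	detection_NT	+	mesophilic	SufBD	FALSE	FALSE
Euryarchaeota	Candidatus Methanomethylophilus alvus Mx1201	-	-	-	-	-	3.0	-	detection_NT	-	?	SufBD	FALSE	FALSE
Fibrobacteres	Chitinivibrio alkaliphilus ACht1	-	-	-	-	-	3.2	-	detection_NT	-	mesophilic	IscU	FALSE	FALSE
Firmicutes	Bacillus subtilis subsp. subtilis str. 168	-	+	+	+	+	3.8	-	NT	+	mesophilic	SufBD	FALSE	TRUE
Firmicutes	Desulfitobacterium hafniense DCB-2	-	-	-	+	+	3.5	-	+	-	mesophilic	IscU	FALSE	FALSE
Firmicutes	Ruminiclostridium cellulolyticum H10	-	-	-	-	-	2.9	-	detection_NT	-	mesophilic	IscU	FALSE	FALSE
Firmicutes	Heliobacterium modesticaldum Ice1	-	-	-	-	-	3.4	-	+	-	thermophilic	IscU	FALSE	FALSE
Nitrospinae	Nitrospina gracilis	+	NT	NT	+	+	3.2	+	NT	+	mesophilic	SufBD	FALSE	FALSE
Planctomycetes	Gemmata obscuriglobus	+	NT	NT	+	+	2.1	-	NT	+	mesophilic	IscU	FALSE	FALSE
Planctomycetes	Pirellula staleyi DSM 6068	-	-	-	-	-	2.7	-	+	+	mesophilic	SufBD	FALSE	FALSE
Proteobacteria	Aeromonas hydrophila	+	NT	NT	+	+	3.8	-	NT	+	mesophilic	IscU	FALSE	FALSE
Proteobacteria	Desulfovibrio vulgaris str. Hildenborough	-	-	-	-	-	3.2	-	detection_NT	-	mesophilic	SufBD, IscU	FALSE	FALSE
Proteobacteria	Allochromatium vinosum	+	NT	NT	+	+	2.9	+	NT	-	mesophilic	SufBD, IscU (NifU)	FALSE	FALSE
Proteobacteria	Arcobacter butzleri	-	-	-	-	-	2.2	-	+	+	mesophilic	SufBD, IscU	FALSE	FALSE
Proteobacteria	Novosphingobium stygium	-	+	+	-	+	2.3	-	NT	+	mesophilic	SufBD	FALSE	FALSE
Proteobacteria	Herminiimonas arsenicoxydans	+	NT	NT	+	+	3.5	-	NT	+	mesophilic	IscU	FALSE	FALSE
Proteobacteria	Chromobacterium violaceum ATCC 12472	+	NT	NT	+	+	3.4	-	NT	+	mesophilic	IscU	FALSE	FALSE
Proteobacteria	Bdellovibrio bacteriovorus HD100	+	NT	NT	+	+	3.9	-	NT	+	mesophilic	SufBD	FALSE	FALSE
Proteobacteria	Methylobacillus flagellatus KT	-	-	-	-	-	4.7	-	+	-	mesophilic	IscU	FALSE	FALSE
Proteobacteria	Anaeromyxobacter dehalogenans 2 CP-C	+	NT	NT	+	+	3.7	-	NT	-	mesophilic	SufBD, IscU	FALSE	FALSE
Proteobacteria	Candidatus Pelagibacter ubique HTCC1002	-	-	-	-	-	3.4	-	detection_NT	+	?	SufBD	FALSE	FALSE
Proteobacteria	Syntrophobacter fumaroxidans MPOB	-	-	-	-	-	3.5	-	detection_NT	-	mesophilic	SufBD, IscU	FALSE	FALSE
Proteobacteria	Cellvibrio japonicus Ueda107	+	NT	NT	+	+	2.9	-	NT	+	mesophilic	SufBD	FALSE	FALSE
Proteobacteria	Escherichia coli str. K-12 substr. MG1655	+	NT	NT	+	+	3.8	+	+	+	mesophilic	SufBD, IscU	TRUE	FALSE
Proteobacteria	Desulfarculus baarsii DSM 2075	-	-	-	-	-	2.8	-	detection_NT	-	mesophilic	IscU	FALSE	FALSE
Proteobacteria	Salinisphaera sp. LB1	+	NT	NT	+	+	4.0	-	NT	+	mesophilic	SufBD	FALSE	FALSE
Spirochaetes	Leptospira interrogans serovar Lai str. 56,601	+	NT	NT	+	+	4.2	+	NT	+	mesophilic	SufBD	FALSE	FALSE
Spirochaetes	Spirochaeta thermophila DSM 6578	-	+	-	-	+	3.2	-	NT	-	thermophilic	SufBD	FALSE	FALSE
Synergistetes	Thermanaerovibrio acidaminovorans DSM 6589	-	-	-	-	-	NT	-	detection_NT	-	thermophilic	SufBD, IscU	FALSE	FALSE
Thermotogae	Thermotoga maritima MSB8	-	-	-	+	+	4.3	-	NT	-	hyperthermophilic	SufBD	FALSE	FALSE
Verrucomicrobia	Coraliomargarita akajimensis DSM 45221	+	NT	NT	+	+	3.6	+	NT	+	mesophilic	SufBD	FALSE	FALSE
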