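#source	mnx_id	evidence	description
MetaCyc:SUC	MNXM25	identity	suc|succinate
Reactome:188980	MNXM167	identity	suc|sucrose
MetaCyc:PROTON	MNXM1	identity	H|proton
MetaCyc:HIS	MNXM134	identity	H|L-histidine
BiGG:tmp	MNXM87343	identity	tmp|TMP
ChEBI:10529	MNXM257	identity	tmp|Thymidine monophosphate
KEGG:C01081	MNXM662	identity	tmp|Thiamine monophosphate
MetaCyc:CPD-610	MNXM88031	identity	tmp|cyclo-triphosphoric acid
Reactome:1475054	MNXM3109	identity	PPP|triphosphate ion
MetaCyc:2-PHENYL-2-1-PIPERDINYLPROPANE	MNXM150634	identity	PPP|2-phenyl-2-1piperdinylpropane
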