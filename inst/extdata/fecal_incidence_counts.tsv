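family	taxon	rank	jul_early	jul_late	aug	sep	oct	total_printed
Apiaceae	Peucedanum multivittatum	species	10	0	0	0	0	10
Apiaceae	Tilingia ajanensis	species	16	4	12	4	0	36
Asteraceae	Asteraceae (Cirsium otayae, Hieracium japonicum, Solidago virgaurea subsp. asiatica)	family	0	0	0	0	2	2
Asteraceae	Ixeridium dentatum subsp. kimuranum	species	4	1	1	1	1	8
Asteraceae	Solidago virgaurea subsp. asiatica	species	0	0	1	0	0	1
Asteraceae	Taraxacum officinale	species	1	0	0	0	0	1
Betulaceae	Alnus hirsuta var. sibirica	species	1	0	0	0	0	1
Betulaceae	Betula ermanii	species	4	0	2	4	2	12
Cephaloziaceae	Alobiellopsis parvifolia	species	1	0	0	0	0	1
Cornaceae	Cornus canadensis	species	0	0	4	0	2	6
Cupressaceae	Juniperus communis var. hondoensis	species	1	1	0	0	0	2
Cyperaceae	Carex blepharicarpa	species	3	5	1	0	0	9
Cyperaceae	Carex oxyandra	species	0	0	1	0	0	1
Cyperaceae	Carex pyrenaica var. altior	species	0	1	0	0	0	1
Diapensiaceae	Schizocodon soldanelloides f. alpinus	species	1	0	1	0	0	2
Ericaceae	Andromeda polifolia	species	0	3	0	0	0	3
Ericaceae	Elliottia bracteata	species	1	0	1	0	0	2
Ericaceae	Empetrum nigrum var. japonicum	species	15	8	28	14	7	72
Ericaceae	Epigaea asiatica	species	0	1	0	0	0	1
Ericaceae	Gaultheria adenothrix	species	0	0	0	3	1	4
Ericaceae	Gaultheria pyroloides	species	0	0	3	0	1	4
Ericaceae	Kalmia procumbens	species	5	16	11	7	6	45
Ericaceae	Phyllodoce sp. (P. aleutica, P. nipponica)	genus	1	0	1	0	0	2
Ericaceae	Phyllodoce aleutica	species	4	0	4	2	4	14
Ericaceae	Phyllodoce nipponica	species	1	1	1	0	0	4
Ericaceae	Vaccinium sp. (V. shikokianum, V. smallii var. smallii, V. uliginosum var. japonicum)	genus	3	5	11	5	0	24
Ericaceae	Vaccinium hirtum	species	0	0	1	0	0	1
Ericaceae	Vaccinium ovalifolium var. ovalifolium	species	28	10	19	8	8	73
Ericaceae	Vaccinium uliginosum var. japonicum	species	14	5	6	6	5	36
Ericaceae	Vaccinium vitis-idaea	species	2	2	5	3	2	14
Fabaceae	Astragalus sinicus	species	1	0	0	0	0	1
Gentianaceae	Gentiana nipponica	species	0	0	1	0	0	1
Gentianaceae	Gentiana thunbergii var. minor	species	0	0	1	0	0	1
Juncaceae	Juncus filiformis	species	0	1	7	0	0	8
Menyanthaceae	Nephrophyllidium crista-galli subsp. japonicum	species	3	7	1	1	0	12
Nartheciaceae	Aletris foliata	species	1	0	0	0	0	1
Nartheciaceae	Narthecium asiaticum	species	0	0	1	0	0	1
Orchidaceae	Dactylorhiza aristata	species	0	1	3	0	0	4
Orobanchaceae	Pedicularis yezoensis	species	2	1	0	0	0	3
Pinaceae	Pinus pumila	species	1	0	0	0	0	1
Poaceae	Bromus sp. (B. inermis, B. pacificus)	genus	0	0	8	0	1	9
Poaceae	Calamagrostis longiseta	species	0	0	1	0	0	1
Poaceae	Sasa kurilensis	species	1	1	13	0	0	15
Polygonaceae	Persicaria weyrichii var. weyrichii	species	1	0	0	0	0	1
Polytrichaceae	Polytrichum juniperinum	species	5	3	4	0	0	12
Ranunculaceae	Aconitum hakusanense	species	0	0	1	0	0	1
Ranunculaceae	Anemone narcissiflora subsp. nipponica	species	1	0	0	0	0	1
Ranunculaceae	Coptis trifoliolata	species	0	0	2	0	0	2
Rosaceae	Potentilla matsumurae	species	2	1	1	2	0	6
Rosaceae	Rubus vernus	species	0	0	0	0	1	1
Rosaceae	Sieversia pentapetala	species	17	1	9	2	2	31
Rosaceae	Sorbus commixta	species	0	0	13	2	1	16
Tofieldiaceae	Triantha japonica	species	0	5	1	0	0	6
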