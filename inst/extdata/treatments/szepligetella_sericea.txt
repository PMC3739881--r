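Szepligetella sericea

Body length.
Body length: 5.5–9.1 mm.

Head.
Median clypeal projection sharpness: pointed.
Lower face texture: foveate.
Median carina of lower face presence: present.
Malar space length: shorter than 0.5 of compound eye height.
Carinae laterally on frons presence: present.
Antennal rim shape: raised laterally.
Antennal shelf presence: absent.
Eye color: gray-silver.
Long setae (length >2× ocellus diameter) presence: absent.
Mandibular teeth count: 4.
Female scape length: equal to eye height.
Female flagellum color pattern: monocolored.
Female flagellum ventral sensillar patch spatial arrangement: F4–F11.

Mesosoma.
Shape of median area of pronotum: recurved.
Sulcus delimiting pronotal lobe presence: absent.
Pronotal lobe carina presence: present.
Anteromedian carina of the prosternum presence: present.
Mesoscutal humeral sulcus continuity: continuous.
Notaulus shape: falciform.
Notaulus lateral margins alignment: parallel.
Median mesoscutal area shape: not prominent relative to lateral mesoscutal area.
Scutoscutellar suture structure: foveate.
Ventro-lateral region of mesosoma texture: areolate.
Anterolateral mesopectal projection 2d shape: isosceles triangular.
Speculum presence: present.
Epicnemium sculpture: wrinkled.
Epicnemial carina shape: concave medially.
Ventral margin of mesopectus length: longer than ventral margin of metapectus length.
Metapleural sulcus position: vertical.
Posterior margin of the propodeum ventrally of the propodeal foramen lateral view shape: straight.
Gastral scrobe conspicuousness: conspicuous.
Lateral carina of gastral scrobe presence: present.
Submedian propodeal projection presence: absent.
Nucha presence: present.
Female metatibial spines presence: present.
1M length versus 1CUb length: equal.
Distal part of 4RS shape: arched distally.
Costal cell coloration: brown in the distal one-tenth.

Metasoma.
Petiole texture: furrowed.
Petiole pilosity: sparse.
Lateroventral carina of the petiole presence: absent.
Setiferous patch on dorsal region of abdominal terga 4–7 in female presence: present.

Material Examined.
Evania sericea only known type male: USA: Hawaii, B.M.TYPE.HYM. 3a.288 (BMNH). Evania impressa syntype female: PHILIPPINES (ZMHB). Other syntypes, deposited at ZMUH, were destroyed during World War II. Other material: FIJI: three males, five females, one sex unknown. NCSU 51433–51436, 51438 (CAS); NCSU 51437, 51439 (USNM); NCSU 53081 (PSUC); NCSU 53082 (BPBM). FRANCE: French Polynesia: 36 males, 3 females. NCSU 49536–49544, 51421–51427, 51429–51432 (CAS); NCSU 49545, 51428 (PSUC); NCSU 49546–49547, 49551, 51396, 51398, 51400, 51442–51445, 51447–51452 (USNM); NCSU 51446 (USNM). INDONESIA: nine males, three females. NCSU 51394, 51402–51411 (CAS); NCSU 51420 (USNM). MALAYSIA: one female. NCSU 51440 (USNM). MARSHALL ISLANDS: seven males, two females. NCSU 51397, 51412–51419 (USNM). PHILIPPINES: one male. NCSU 51401 (USNM). USA: one male. NCSU 51395 (USNM). USA: Hawaii: one male, one female. NCSU 49554, 51393 (USNM). USA: Hawaii: Hawaii Co.: nine males. NCSU 34866, 49548–49549, 51386–51391 (USNM). USA: Hawaii: Honolulu Co.: two males, two females. NCSU 51385 (CAS); NCSU 49553, 51392, 51441 (USNM). USA: Hawaii: Maui Co.: one male, one female. NCSU 49552 (CAS); NCSU 49555 (PSUC). VANUATU: one female. NCSU 49550 (CAS).
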