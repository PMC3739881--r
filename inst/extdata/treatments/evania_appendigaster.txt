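Evania appendigaster

Body length.
Body length: 7.0–7.8 mm.

Head.
Median clypeal projection sharpness: blunt.
Lower face texture: foveae absent.
Median carina of lower face presence: absent.
Malar space length: longer than 0.5 of compound eye height.
Carinae laterally on frons presence: absent.
Antennal rim shape: not raised laterally.
Antennal shelf presence: present.
Eye color: blue.
Long setae (length >2× ocellus diameter) presence: absent.
Mandibular teeth count: 3.
Female scape length: greater than eye height.
Female flagellum color pattern: monocolored.
Female flagellum ventral sensillar patch spatial arrangement: F5–F11.

Mesosoma.
Shape of median area of pronotum: not recurved.
Sulcus delimiting pronotal lobe presence: present.
Pronotal lobe carina presence: absent.
Anteromedian carina of the prosternum presence: absent.
Mesoscutal humeral sulcus continuity: discontinuous.
Notaulus shape: sigmoid.
Notaulus lateral margins alignment: parallel.
Median mesoscutal area shape: not prominent relative to lateral mesoscutal area.
Scutoscutellar suture structure: not foveate.
Ventro-lateral region of mesosoma texture: foveate.
Anterolateral mesopectal projection 2d shape: scalene triangular.
Speculum presence: absent.
Epicnemium sculpture: smooth.
Epicnemial carina shape: convex medially.
Ventral margin of mesopectus length: shorter than ventral margin of metapectus length.
Metapleural sulcus position: horizontal.
Posterior margin of the propodeum ventrally of the propodeal foramen lateral view shape: convex.
Gastral scrobe conspicuousness: inconspicuous.
Lateral carina of gastral scrobe presence: absent.
Submedian propodeal projection presence: absent.
Nucha presence: absent.
Female metatibial spines presence: absent.
1M length versus 1CUb length: 1M is distinctly longer than 1CUb.
Distal part of 4RS shape: straight or arched proximally.
Costal cell coloration: brown in the distal one-tenth.

Metasoma.
Petiole texture: smooth.
Petiole pilosity: dense.
Lateroventral carina of the petiole presence: present.
Setiferous patch on dorsal region of abdominal terga 4–7 in female presence: present.

Material Examined.
Syntype male: {no locality label} LINN 2719 (LSUK). Syntype female: {no locality label} LINN 2720 (LSUK). Other material: FRANCE: New Caledonia: one female. NCSU 49532 (PSUC). USA: TX: Brazos Co.: one female. NCSU 23566 (PSUC).
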