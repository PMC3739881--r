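Szepligetella levipetiolata

Body length.
Body length: 4.6–8.0 mm.

Head.
Median clypeal projection sharpness: pointed.
Lower face texture: foveae absent.
Median carina of lower face presence: present.
Malar space length: shorter than 0.5 of compound eye height.
Carinae laterally on frons presence: present.
Antennal rim shape: raised laterally.
Antennal shelf presence: absent.
Eye color: gray-silver.
Long setae (length >2× ocellus diameter) presence: absent.
Mandibular teeth count: 4.
Female scape length: greater than eye height.
Female flagellum color pattern: banded.
Female flagellum ventral sensillar patch spatial arrangement: F6–F11.

Mesosoma.
Shape of median area of pronotum: recurved.
Sulcus delimiting pronotal lobe presence: absent.
Pronotal lobe carina presence: present.
Anteromedian carina of the prosternum presence: present.
Mesoscutal humeral sulcus continuity: continuous.
Notaulus shape: sigmoid.
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
Gastral scrobe conspicuousness: inconspicuous.
Lateral carina of gastral scrobe presence: absent.
Submedian propodeal projection presence: present.
Nucha presence: present.
Female metatibial spines presence: absent; present.
1M length versus 1CUb length: 1M is distinctly longer than 1CUb.
Distal part of 4RS shape: straight or arched proximally.
Costal cell coloration: brown in the distal one-half–two-third.

Metasoma.
Petiole texture: smooth.
Petiole pilosity: sparse.
Lateroventral carina of the petiole presence: absent.
Setiferous patch on dorsal region of abdominal terga 4–7 in female presence: present.

Material Examined.
Holotype male: FRANCE: New Caledonia, B.M.TYPE.HYM. 3a.287 (BMNH). Other material: FRANCE: New Caledonia: 87 males, 1 female (NCSU 41656). NCSU 51293 (CAS); NCSU 34829, 34842, 34848, 34860, 41650, 41654, 41656, 44107, 44114, 44116, 44119, 44124, 51298 (PSUC); NCSU 33643, 41652–41653, 41655, 41657, 41661–41662, 41665–41666, 41669, 41897–41898, 44100, 44103, 44108, 44110–44112, 44115, 44117, 44120, 44122–44123, 44125–44126, 44129, 51297, 51299 (MNHN); NCSU 34828, 34830–34841, 34843–34847, 34849–34859, 34861–34865, 41658, 41668, 44101–44102, 44104–44106, 44109, 44127, 51296 (INHS); NCSU 51294–51295 (CNC).
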