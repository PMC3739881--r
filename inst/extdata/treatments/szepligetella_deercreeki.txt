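Szepligetella deercreeki

Body length.
Body length: 5.3–6.6 mm.

Head.
Median clypeal projection sharpness: pointed.
Lower face texture: foveate.
Median carina of lower face presence: absent.
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
Notaulus shape: sigmoid.
Notaulus lateral margins alignment: diverging.
Median mesoscutal area shape: prominent relative to lateral mesoscutal area.
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
Lateral carina of gastral scrobe presence: absent.
Submedian propodeal projection presence: absent.
Nucha presence: present.
Female metatibial spines presence: present.
1M length versus 1CUb length: 1M is distinctly longer than 1CUb.
Distal part of 4RS shape: straight or arched proximally.
Costal cell coloration: brown in the distal one-tenth; brown in the distal one-half–two-third.

Metasoma.
Petiole texture: smooth.
Petiole pilosity: sparse.
Lateroventral carina of the petiole presence: absent.
Setiferous patch on dorsal region of abdominal terga 4–7 in female presence: absent.

Material Examined.
Holotype: (female): FRANCE: New Caledonia: NCSU 43287 (CNC). Paratypes (four males): FRANCE: New Caledonia: NCSU 41660 (CNC), NCSU 49529–49531 (BMNH).
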