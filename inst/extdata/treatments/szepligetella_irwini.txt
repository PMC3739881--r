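Szepligetella irwini

Body length.
Body length: 6.5–6.8 mm.

Head.
Median clypeal projection sharpness: pointed.
Lower face texture: foveae absent.
Median carina of lower face presence: present.
Malar space length: shorter than 0.5 of compound eye height.
Carinae laterally on frons presence: present.
Antennal rim shape: raised laterally.
Antennal shelf presence: absent.
Eye color: gray-silver.
Long setae (length >2× ocellus diameter) presence: present.
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
Posterior margin of the propodeum ventrally of the propodeal foramen lateral view shape: convex.
Gastral scrobe conspicuousness: inconspicuous.
Lateral carina of gastral scrobe presence: absent.
Submedian propodeal projection presence: present.
Nucha presence: present.
Female metatibial spines presence: absent.
1M length versus 1CUb length: 1M is distinctly longer than 1CUb.
Distal part of 4RS shape: straight or arched proximally.
Costal cell coloration: brown in the distal one-half–two-third.

Metasoma.
Petiole texture: smooth.
Petiole pilosity: sparse.
Lateroventral carina of the petiole presence: absent.
Setiferous patch on dorsal region of abdominal terga 4–7 in female presence: absent.

Material Examined.
Holotype female: FRANCE: New Caledonia: NCSU 41664 (MNHN). Paratype female: FRANCE: New Caledonia: 44113 (INHS).
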