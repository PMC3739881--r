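state	expression
Eye color: blue	has_part some (eye and bearer_of some blue)
Eye color: gray-silver	has_part some (eye and bearer_of some 'gray-silver')
Ventro-lateral region of mesosoma texture: foveate	has_part some (mesosoma and has_part some ('ventro-lateral region' and bearer_of some foveate))
Ventro-lateral region of mesosoma texture: areolate	has_part some (mesosoma and has_part some ('ventro-lateral region' and bearer_of some areolate))
Mandibular teeth count: 3	has_part some (mandible and has_part exactly 3 tooth)
Mandibular teeth count: 4	has_part some (mandible and has_part exactly 4 tooth)
Nucha presence: present	has_part some nucha
Nucha presence: absent	has_part some (propodeum and bearer_of some absent)
Speculum presence: present	has_part some (mesosoma and has_part some speculum)
Speculum presence: absent	has_part some (mesosoma and bearer_of some absent)
Antennal shelf presence: present	has_part some 'antennal shelf'
Antennal shelf presence: absent	has_part some (head and bearer_of some absent)
Female metatibial spines presence: present	has_part some (leg and has_part some 'metatibial spine')
Female metatibial spines presence: absent	has_part some (leg and bearer_of some absent)
Notaulus shape: sigmoid	has_part some (notaulus and bearer_of some sigmoid)
Notaulus shape: falciform	has_part some (notaulus and bearer_of some falciform)
Petiole texture: smooth	has_part some (petiole and bearer_of some smooth)
Petiole texture: furrowed	has_part some (petiole and bearer_of some furrowed)
Ventral margin of mesopectus length: shorter than ventral margin of metapectus length	has_part some (mesopectus and bearer_of some (length and towards some metapectus))
Ventral margin of mesopectus length: longer than ventral margin of metapectus length	has_part some (mesopectus and bearer_of some (length and towards some metapectus))
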