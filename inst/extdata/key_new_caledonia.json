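{
  "name": "Identification key to the ensign wasps of New Caledonia and the Pacific",
  "root": "1",
  "couplets": [
    {
      "id": "1",
      "leads": [
        {
          "tests": [
            ["Antennal shelf presence", "present"],
            ["Eye color", "blue"],
            ["Malar space length", "longer than 0.5 of compound eye height"],
            ["Ventro-lateral region of mesosoma texture", "foveate"],
            ["Ventral margin of mesopectus length", "shorter than ventral margin of metapectus length"]
          ],
          "taxon": "Evania appendigaster"
        },
        {
          "tests": [
            ["Antennal shelf presence", "absent"],
            ["Eye color", "gray-silver"],
            ["Malar space length", "shorter than 0.5 of compound eye height"],
            ["Ventro-lateral region of mesosoma texture", "areolate"],
            ["Ventral margin of mesopectus length", "longer than ventral margin of metapectus length"]
          ],
          "couplet": "2"
        }
      ]
    },
    {
      "id": "2",
      "leads": [
        {
          "tests": [
            ["Female flagellum color pattern", "banded"],
            ["Carinae laterally on frons presence", "present"],
            ["Lower face texture", "foveae absent"],
            ["Female scape length", "greater than eye height"],
            ["Female flagellum ventral sensillar patch spatial arrangement", "F6–F11"],
            ["Submedian propodeal projection presence", "present"]
          ],
          "couplet": "3"
        },
        {
          "tests": [
            ["Female flagellum color pattern", "monocolored"],
            ["Carinae laterally on frons presence", "present"],
            ["Lower face texture", "foveate"],
            ["Female scape length", "equal to eye height"],
            ["Female flagellum ventral sensillar patch spatial arrangement", "F4–F11"],
            ["Submedian propodeal projection presence", "absent"]
          ],
          "couplet": "4"
        }
      ]
    },
    {
      "id": "3",
      "leads": [
        {
          "tests": [
            ["Long setae (length >2× ocellus diameter) presence", "present"],
            ["Female metatibial spines presence", "absent"]
          ],
          "taxon": "Szepligetella irwini"
        },
        {
          "tests": [
            ["Long setae (length >2× ocellus diameter) presence", "absent"],
            ["Female metatibial spines presence", "present"]
          ],
          "taxon": "Szepligetella levipetiolata"
        }
      ]
    },
    {
      "id": "4",
      "leads": [
        {
          "tests": [
            ["Notaulus shape", "falciform"],
            ["Notaulus lateral margins alignment", "parallel"],
            ["Median mesoscutal area shape", "not prominent relative to lateral mesoscutal area"],
            ["Lateral carina of gastral scrobe presence", "present"],
            ["Petiole texture", "furrowed"],
            ["Setiferous patch on dorsal region of abdominal terga 4–7 in female presence", "present"]
          ],
          "taxon": "Szepligetella sericea"
        },
        {
          "tests": [
            ["Notaulus shape", "sigmoid"],
            ["Notaulus lateral margins alignment", "diverging"],
            ["Median mesoscutal area shape", "prominent relative to lateral mesoscutal area"],
            ["Lateral carina of gastral scrobe presence", "absent"],
            ["Petiole texture", "smooth"],
            ["Setiferous patch on dorsal region of abdominal terga 4–7 in female presence", "absent"]
          ],
          "taxon": "Szepligetella deercreeki"
        }
      ]
    }
  ]
}
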