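agreement,notes
Convention on International Trade in Endangered Species,CITES
Convention on the Conservation of Migratory Species,CMS / Bonn Convention
EU Wildlife Trade Regulations,EU annexes
Bern Convention,Convention on the Conservation of European Wildlife and Natural Habitats
EU Habitats Directive,Council Directive 92/43/EEC
EU Birds Directive,Directive 2009/147/EC
Ramsar Convention,Convention on Wetlands
Agreement on the Conservation of Albatrosses and Petrels,ACAP
African-Eurasian Migratory Waterbird Agreement,AEWA
Western Hemisphere Convention,Convention on Nature Protection and Wild Life Preservation in the Western Hemisphere
Apia Convention,Convention on Conservation of Nature in the South Pacific
ASEAN Agreement on the Conservation of Nature and Natural Resources,ASEAN
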