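code,cbd_category,notes
1,habitat_loss,Residential & commercial development
1.1,habitat_loss,Housing & urban areas
1.2,habitat_loss,Commercial & industrial areas
1.3,habitat_loss,Tourism & recreation areas
2,habitat_loss,Agriculture & aquaculture
2.1,habitat_loss,Annual & perennial non-timber crops
2.2,habitat_loss,Wood & pulp plantations
2.3,habitat_loss,Livestock farming & ranching
2.4,habitat_loss,Marine & freshwater aquaculture
3,habitat_loss,Energy production & mining
3.1,habitat_loss,Oil & gas drilling
3.2,habitat_loss,Mining & quarrying
3.3,habitat_loss,Renewable energy
4,habitat_loss,Transportation & service corridors
4.1,habitat_loss,Roads & railroads
4.2,habitat_loss,Utility & service lines
4.3,habitat_loss,Shipping lanes
4.4,habitat_loss,Flight paths
5,overexploitation,Biological resource use
5.1,overexploitation,Hunting & collecting terrestrial animals
5.2,overexploitation,Gathering terrestrial plants
5.3,habitat_loss,Logging & wood harvesting
5.4,overexploitation,Fishing & harvesting aquatic resources
6,habitat_loss,Human intrusions & disturbance
6.1,habitat_loss,Recreational activities
6.2,habitat_loss,War & civil unrest & military exercises
6.3,habitat_loss,Work & other activities
7,habitat_loss,Natural system modifications
7.1,habitat_loss,Fire & fire suppression
7.2,habitat_loss,Dams & water management or use
7.3,habitat_loss,Other ecosystem modifications
8,invasive_species,Invasive & other problematic species genes & diseases
8.1,invasive_species,Invasive non-native or alien species and diseases
8.2,other,Problematic native species and diseases
8.3,other,Introduced genetic material
8.4,invasive_species,Problematic species or diseases of unknown origin
8.5,other,Viral or prion-induced diseases
8.6,other,Diseases of unknown cause
9,pollution,Pollution
9.1,pollution,Domestic & urban waste water
9.2,pollution,Industrial & military effluents
9.3,pollution,Agricultural & forestry effluents
9.4,pollution,Garbage & solid waste
9.5,pollution,Air-borne pollutants
9.6,pollution,Excess energy
10,other,Geological events
10.1,other,Volcanoes
10.2,other,Earthquakes and tsunamis
10.3,other,Avalanches and landslides
11,climate_change,Climate change & severe weather
11.1,climate_change,Habitat shifting & alteration
11.2,climate_change,Droughts
11.3,climate_change,Temperature extremes
11.4,climate_change,Storms & flooding
11.5,climate_change,Other impacts
12,other,Other options
12.1,other,Other threat
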