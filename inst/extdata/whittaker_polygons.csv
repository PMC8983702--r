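biome,vertex,mat_c,map_cm
tundra,1,-15,0
tundra,2,-5,0
tundra,3,-5,100
boreal forest,1,-5,0
boreal forest,2,3,0
boreal forest,3,3,180
boreal forest,4,-5,100
temperate grassland/desert,1,3,0
temperate grassland/desert,2,20,0
temperate grassland/desert,3,20,70
temperate grassland/desert,4,3,40
subtropical desert,1,20,0
subtropical desert,2,30,0
subtropical desert,3,30,70
subtropical desert,4,20,70
woodland/shrubland,1,3,40
woodland/shrubland,2,20,70
woodland/shrubland,3,20,120
woodland/shrubland,4,3,70
tropical seasonal forest/savanna,1,20,70
tropical seasonal forest/savanna,2,30,70
tropical seasonal forest/savanna,3,30,250
tropical seasonal forest/savanna,4,20,250
tropical rain forest,1,20,250
tropical rain forest,2,30,250
tropical rain forest,3,30,450
tropical rain forest,4,20,350
temperate seasonal forest,1,3,70
temperate seasonal forest,2,20,120
temperate seasonal forest,3,20,200
temperate seasonal forest,4,5,200
temperate seasonal forest,5,3,180
temperate rain forest,1,5,200
temperate rain forest,2,20,200
temperate rain forest,3,20,350
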