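family,species,common_name,epp
Acrocephalidae,Acrocephalus arundinaceus,Great reed warbler,6.00
Acrocephalidae,Acrocephalus schoenobaenus,Sedge warbler,25.47
Acrocephalidae,Cardinalis cardinalis,Northern cardinal,13.51
Acrocephalidae,Passerina cyanea,Indigo bunting,70.00
Emberizidae,Emberiza citrinella,Yellowhammer,69.00
Emberizidae,Emberiza schoeniclus,Common reed bunting,64.00
Emberizidae,Junco hyemalis,Dark-eyed junco,28.34
Emberizidae,Melospiza melodia,Song sparrow,8.80
Emberizidae,Passerculus sandwichensis,Savannah sparrow,50.80
Emberizidae,Spizella pusilla,Field sparrow,15.10
Emberizidae,Zonotrichia albicollis,White-throated sparrow,12.80
Emberizidae,Zonotrichia leucophrys,White-crowned sparrow,31.00
Fringillidae,Fringilla coelebs,Common chaffinch,17.00
Fringillidae,Haemorhous mexicanus,House finch,14.30
Hirundidae,Hirundo rustica,Barn swallow,45.30
Hirundidae,Progne subis,Purple martin,27.50
Icteridae,Agelaius phoeniceus,Red-winged blackbird,55.00
Icteridae,Dolichonyx oryzivorus,Bobolink,38.00
Mimidae,Mimus polyglottos,Northern mockingbird,8.00
Motacillidae,Anthus spinoletta,Water pipit,12.40
Muscicapidae,Ficedula albicollis,Collared flycatcher,38.95
Muscicapidae,Ficedula hypoleuca,European pied flycatcher,14.50
Muscicapidae,Luscinia svecica,Bluethroat,51.50
Muscicapidae,Oenanthe oenanthe,Northern wheatear,29.00
Paridae,Poecile atricapillus,Black-capped chickadee,28.15
Paridae,Cyanistes caeruleus,Eurasian blue tit,49.18
Paridae,Parus major,Great tit,33.28
Parulidae,Setophaga petechia,Mangrove warbler,53.80
Parulidae,Setophaga ruticilla,American redstart,59.00
Parulidae,Setophaga citrina,Hooded warbler,35.30
Prunellidae,Prunella modularis,Dunnock,0.80
Sylviidae,Phylloscopus sibilatrix,Wood warbler,0.00
Sylviidae,Phylloscopus trochilus,Willow warbler,18.52
Troglodytidae,Troglodytes aedon,House wren,42.67
Turdidae,Turdus merula,Common blackbird,17.77
Vireonidae,Vireo solitarius,Blue-headed vireo,2.70
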