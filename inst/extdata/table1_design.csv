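species,family,growth_form,native_to,invasive_in,pops_france,pops_japan,pops_usa
Daucus carota,Apiaceae,herbaceous,France,,5,0,0
Eupatorium cannabinum,Asteraceae,herbaceous,France,,5,0,0
Senecio jacobaea,Asteraceae,herbaceous,France,,5,0,0
Senecio vulgaris,Asteraceae,herbaceous,France,,5,0,0
Humulus lupulus,Cannabinaceae,woody,France,,5,0,0
Laburnum anagyroides,Fabaceae,woody,France,,6,0,0
Quercus robur,Fagaceae,woody,France,,5,0,0
Acer pseudoplatanus,Sapindaceae,woody,France,,6,0,0
Chenopodium album,Amaranthaceae,herbaceous,France,Japan/USA,6,4,0
Leucanthemum vulgare,Asteraceae,herbaceous,France,Japan/USA,5,10,5
Plantago lanceolata,Plantaginaceae,herbaceous,France,Japan/USA,6,5,5
Agrostis gigantea,Poaceae,herbaceous,France,Japan/USA,5,5,0
Agrostis stolonifera,Poaceae,herbaceous,France,Japan/USA,5,5,0
Artemisia vulgaris,Asteraceae,herbaceous,France,USA,5,0,5
Anthoxanthum odoratum,Poaceae,herbaceous,France,USA,5,5,0
Dactylis glomerata,Poaceae,herbaceous,France,USA,5,0,0
Rhamnus cathartica,Rhamnaceae,woody,France,USA,5,0,6
Prunus avium,Rosaceae,woody,France,USA,6,0,4
Solidago virgaurea,Asteraceae,herbaceous,France/Japan,,3,5,0
Cirsium japonicum,Asteraceae,herbaceous,Japan,,0,4,0
Eupatorium glehnii,Asteraceae,herbaceous,Japan,,0,5,0
Youngia japonica,Asteraceae,herbaceous,Japan,,0,4,0
Plantago asiatica,Plantaginaceae,herbaceous,Japan,,0,5,0
Viburnum dilatatum,Adoxaceae,woody,Japan,USA,0,5,5
Berberis thunbergii,Berberidaceae,woody,Japan,USA,0,8,5
Lonicera japonica,Caprifoliaceae,woody,Japan,USA,0,4,5
Lonicera morrowii,Caprifoliaceae,woody,Japan,USA,0,3,5
Celastrus orbiculatus,Celastraceae,woody,Japan,USA,0,4,5
Euonymus alatus,Celastraceae,woody,Japan,USA,0,5,4
Rosa multiflora,Rosaceae,woody,Japan,USA,0,4,5
Bidens tripartita,Asteraceae,herbaceous,USA,,3,0,0
Viburnum acerifolium,Adoxaceae,woody,USA,,0,0,5
Lonicera canadensis,Caprifoliaceae,woody,USA,,0,0,4
Lindera benzoin,Lauraceae,woody,USA,,0,0,5
Robinia pseudoacacia,Fabaceae,woody,USA,France,6,0,10
Quercus rubra,Fagaceae,woody,USA,France,5,0,5
Prunus serotina,Rosaceae,woody,USA,France,5,0,5
Acer negundo,Sapindaceae,woody,USA,France,5,0,10
Parthenocissus quinquefolia,Vitaceae,woody,USA,France,7,0,5
Ambrosia artemisiifolia,Asteraceae,herbaceous,USA,France/Japan,5,5,5
Bidens frondosa,Asteraceae,herbaceous,USA,France/Japan,5,5,3
Conyza canadensis,Asteraceae,herbaceous,USA,France/Japan,6,5,6
Erigeron annuus,Asteraceae,herbaceous,USA,France/Japan,5,5,4
Solidago gigantea,Asteraceae,herbaceous,USA,France/Japan,5,4,6
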