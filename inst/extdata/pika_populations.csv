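population,region,n,elevation_m,latitude,longitude
Bodie,CA,15,2500,38.211861,-119.005037
Pipet Tarn,CA,20,3170,37.945285,-119.28413
West Knoll,CO,21,3612,40.056753,-105.59571
Emerald Lake,MT,21,2896,45.407061,-110.93998
Swan Creek,MT,7,1829,45.374392,-111.14408
Overland Lake,NV,17,2281,40.458067,-115.45524
Island Lake,NV,16,3245,40.616662,-115.37916
Hidden Lake,NV,15,3051,40.746363,-115.2845
Week's Creek,NV,10,2825,40.928332,-115.11273
Lizzie's Basin,NV,10,2803,40.943973,-115.11243
Smith Lake,NV,19,2882,41.034497,-115.094786
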