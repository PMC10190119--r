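"building_id","room_id","assessment_date","observer_id","n_components","ceiling_total","walls_total","floor_total","windows_total","furnishings_total","hvac_total","supplies_materials_total","pipes_total","odor_score","room_total","avg_water_damage_stains","avg_visible_mold","avg_wet_damp","room_average","color_band"
"A","101","2024-05-01","obs1",4,3,1,0,1,,,,,1,6,"0.750000","0.250000","0.250000","2.250000","yellow"
"A","102","2024-05-01","obs1",3,0,0,0,,,,,,0,0,"0.000000","0.000000","0.000000","0.000000","none"
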