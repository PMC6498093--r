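compartment	rank	feature_id
whole_plasma	1	hsa-miR-223-3p
whole_plasma	2	hsa-miR-501-5p
whole_plasma	3	hsa-miR-130b-3p
whole_plasma	4	hsa-miR-5010-5p
whole_plasma	5	hsa-miR-330-5p
whole_plasma	6	hsa-miR-378f
whole_plasma	7	hsa-miR-3158-3p
whole_plasma	8	hsa-miR-542-3p
whole_plasma	9	hsa-miR-183-5p
whole_plasma	10	hsa-miR-942-5p
EV	1	hsa-miR-23b-3p
EV	2	hsa-miR-548ac
EV	3	hsa-miR-3126-3p
EV	4	hsa-miR-15b-5p
EV	5	hsa-miR-205-5p
EV	6	hsa-miR-5010-5p
EV	7	hsa-miR-331-5p
EV	8	hsa-miR-1249-3p
EV	9	hsa-miR-548c-5p
EV	10	hsa-miR-1827
EV_free	1	hsa-miR-511-3p
EV_free	2	hsa-miR-376a-3p
EV_free	3	hsa-miR-3150b-3p
EV_free	4	hsa-miR-3150b-5p
EV_free	5	hsa-miR-3168
EV_free	6	hsa-miR-98-5p
EV_free	7	hsa-miR-3136-5p
EV_free	8	hsa-miR-210-5p
EV_free	9	hsa-miR-340-3p
EV_free	10	hsa-miR-636
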