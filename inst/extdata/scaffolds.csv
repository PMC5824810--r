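name,arc_length_nm,angle_deg,radius_nm,curvature_per_um,footprint_nm2,n_anchors,anchor_face
H,110,131,46,21.7,1800,3,concave
Q,110,73,84,11.9,1800,3,concave
L,110,,,0,1800,3,concave
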