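# Canonical 89-marker seated marker layout.
# 7 circumferential rows; 5 columns per sheet (front and back); right and
# left lateral markers on every row; 5 extra pelvic-ring markers in row 7.
rows = 7
front_cols = 5
back_cols = 5
lateral_right_rows = 1:7
lateral_left_rows = 1:7
extra_row = 7
extra_angles = 15,105,195,285,345
# anatomical reference rows (angle of Louis, xiphoid, umbilicus)
level_louis = 2
level_xiphoid = 4
level_umbilicus = 6
# compartment row ranges; adjacent compartments share their boundary row
rows_rcp = 1:4
rows_rca = 4:5
rows_ab = 5:7
total_markers = 89
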