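column,unit,description
species,text,Species or record label
group,text,Locomotor group: diver | flier | swimmer (bat and bird are fliers; fish are swimmers)
mass,kg,Body mass
a,m,Spheroid semi-major axis (divers)
b,m,Spheroid semi-minor axis (divers)
H,m,Jump height above the surface (divers)
orientation,text,Water-entry orientation: head_first | belly_first (divers)
A,m,Stroke amplitude (half peak-to-peak tip displacement)
f,Hz,Stroke frequency
chord_half,m,Chord half-length of the wing or fin section
span,m,Wing span or fin length
body_length,m,Body length (characteristic length for the Reynolds number)
U_swim,m/s,Observed forward swimming speed
weight,N,Body weight (mass times g)
medium,text,Fluid medium: freshwater | seawater | air
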