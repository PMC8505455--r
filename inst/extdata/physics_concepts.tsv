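label	category	elementary
acceleration	classical	TRUE
centripetal force	classical	TRUE
gravity	classical	TRUE
torque	classical	TRUE
velocity	classical	TRUE
direct current	classical	TRUE
electric field	classical	TRUE
force	classical	TRUE
potential energy	classical	TRUE
voltage	classical	TRUE
frequency	classical	TRUE
light	classical	TRUE
radio waves	classical	TRUE
sound waves	classical	TRUE
wavelength	classical	TRUE
buoyancy	classical	FALSE
Coriolis force	classical	FALSE
fractal dimension	classical	FALSE
Lagrangian	classical	FALSE
Hamiltonian	classical	FALSE
precession	classical	FALSE
canonical ensemble	classical	FALSE
conduction	classical	FALSE
crystal lattice	classical	FALSE
diamagnetism	classical	FALSE
insulator	classical	FALSE
boson	post-classical	FALSE
fermion	post-classical	FALSE
muon	post-classical	FALSE
neutrino	post-classical	FALSE
particle decay	post-classical	FALSE
anti-particle	post-classical	FALSE
cosmology	post-classical	FALSE
dark matter	post-classical	FALSE
multiverse	post-classical	FALSE
quasar	post-classical	FALSE
gamma ray	post-classical	FALSE
inertial frame	post-classical	FALSE
Lorentz invariant	post-classical	FALSE
simultaneity	post-classical	FALSE
tachyon	post-classical	FALSE
coherence	post-classical	FALSE
commutator	post-classical	FALSE
duality	post-classical	FALSE
wave function	post-classical	FALSE
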