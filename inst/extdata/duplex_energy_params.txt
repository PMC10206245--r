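# Nearest-neighbor duplex free-energy parameters (Delta G at 37 C, kcal/mol)
#
# Simplified intermolecular hybridization model: Watson-Crick + G:U stack
# free energies from the Turner 2004 nearest-neighbor set, generic
# length-dependent bulge and internal-loop penalties with a capped
# asymmetry term, and a single duplex initiation penalty. No terminal-AU
# penalty, dangling ends, or special small internal-loop tables.
#
# stack <p1> <p2> <dG>
#   p1 = base pair at helix position i, written (query base, target base)
#   p2 = base pair at position i+1 (one step toward the query 3' end)
#   Satisfies nearest-neighbor symmetry: E(p1, p2) = E(rev p2, rev p1),
#   rev(XY) = YX. Checked when the table is loaded.
init 4.09
asym_slope 0.60
asym_max 3.00
maxloop 15
stack CG CG -3.30
stack CG GC -2.40
stack CG GU -1.40
stack CG UG -2.10
stack CG AU -2.10
stack CG UA -2.10
stack GC CG -3.40
stack GC GC -3.30
stack GC GU -1.50
stack GC UG -2.50
stack GC AU -2.40
stack GC UA -2.20
stack GU CG -2.50
stack GU GC -2.10
stack GU GU -0.50
stack GU UG 1.30
stack GU AU -1.30
stack GU UA -1.40
stack UG CG -1.50
stack UG GC -1.40
stack UG GU 0.30
stack UG UG -0.50
stack UG AU -1.00
stack UG UA -0.60
stack AU CG -2.20
stack AU GC -2.10
stack AU GU -0.60
stack AU UG -1.40
stack AU AU -0.90
stack AU UA -1.10
stack UA CG -2.40
stack UA GC -2.10
stack UA GU -1.00
stack UA UG -1.30
stack UA AU -1.30
stack UA UA -0.90
# bulge <total unpaired length> <dG>
bulge 1 3.80
bulge 2 2.80
bulge 3 3.20
bulge 4 3.60
bulge 5 4.00
bulge 6 4.40
bulge 7 4.60
bulge 8 4.70
bulge 9 4.80
bulge 10 4.90
bulge 11 5.00
bulge 12 5.10
bulge 13 5.20
bulge 14 5.30
bulge 15 5.40
# internal <total unpaired length> <dG>  (asymmetry added separately)
internal 2 1.00
internal 3 1.00
internal 4 1.10
internal 5 2.00
internal 6 2.00
internal 7 2.10
internal 8 2.30
internal 9 2.40
internal 10 2.50
internal 11 2.60
internal 12 2.70
internal 13 2.80
internal 14 2.90
internal 15 2.90
internal 16 3.00
internal 17 3.10
internal 18 3.10
internal 19 3.20
internal 20 3.30
internal 21 3.30
internal 22 3.40
internal 23 3.40
internal 24 3.50
internal 25 3.50
internal 26 3.50
internal 27 3.60
internal 28 3.60
internal 29 3.70
internal 30 3.70
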