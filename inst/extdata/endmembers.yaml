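# Endmember signatures of freshly produced N2O and net isotope effects of
# N2O reduction, for the dual-isotope (SP vs d18O) mapping approach.
#
# Values are literature-compilation means +/- SD (permil) for pure-culture /
# controlled studies of each process. d18O of the denitrification-family
# processes (bD, fD, nD) is given RELATIVE TO THE PROCESS WATER, because
# their N2O oxygen derives predominantly from H2O; before mapping, these
# rows must be shifted by the measured d18O of the local water
# (adjust_endmembers()). Nitrification (Ni) d18O derives from atmospheric O2
# and is given on the VSMOW scale directly; it is never water-adjusted.
#
# Edit freely; every mapping result records a hash of the table in use.
version: 1
endmembers:
  bD:                    # heterotrophic bacterial denitrification
    sp_mean: -1.6
    sp_sd: 3.6
    d18o_mean: 17.5      # vs process water until adjusted
    d18o_sd: 3.3
  fD:                    # fungal denitrification
    sp_mean: 34.1
    sp_sd: 3.3
    d18o_mean: 43.5
    d18o_sd: 4.5
  nD:                    # nitrifier denitrification
    sp_mean: -4.9
    sp_sd: 5.5
    d18o_mean: 15.0
    d18o_sd: 5.0
  Ni:                    # nitrification (NH2OH oxidation route)
    sp_mean: 32.4
    sp_sd: 3.1
    d18o_mean: 37.5     # vs VSMOW (O2-derived), not water-adjusted
    d18o_sd: 5.0
reduction:
  eps_sp: -5.9           # net isotope effect of N2O -> N2 on SP
  eps_o: -15.9           # same on d18O; slope eps_sp/eps_o ~ 0.37
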