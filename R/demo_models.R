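rxn <- function(id, k, reactants = NULL, stoich, stim = 0) {
  list(id = id, k = k, reactants = reactants, stoich = stoich, stim = stim)
}

#' Reduced JAK-STAT/SOCS demo model (steady-state responder)
#'
#' A 10-state mass-action reduction of cytokine (IL-6-like) JAK-STAT
#' signalling with its SOCS negative feedback. The stimulus activates a free
#' receptor; the active receptor phosphorylates a preexisting cytoplasmic
#' transcription-factor precursor (STAT3c); phospho-STAT dimerises and the
#' dimer enters the nucleus (nuclear dimer = output 1). A preexisting nuclear
#' phosphatase dephosphorylates the nuclear dimer and recycles it to the
#' cytoplasmic precursor. The nuclear dimer drives transcription and
#' translation of an inhibitor (SOCS, output 2) that reversibly sequesters
#' the active receptor, closing the negative feedback loop; mRNA and
#' inhibitor decay first-order. Under nominal stimulus the nuclear dimer
#' rises to a single peak then relaxes to a nonzero steady state, and SOCS
#' rises to a plateau, within the 10 h default horizon.
#'
#' Preexisting species: free receptor (`Rec`), precursor (`STAT3c`),
#' phosphatase (`PP`). Units: nM and seconds.
#'
#' @return a `kin_model` with outputs `DimN` (nuclear dimer) and `SOCS`.
#' @export
build_demo_steady <- function() {
  init <- c(Rec = 100, RecA = 0, STAT3c = 1000, STAT3p = 0,
            DimC = 0, DimN = 0, PP = 100, mRNA = 0, SOCS = 0,
            RecA_SOCS = 0)
  reactions <- list(
    rxn("r_act",    2e-4, c(Rec = 1),               c(Rec = -1, RecA = 1), stim = 1),
    rxn("r_deact",  1e-3, c(RecA = 1),              c(RecA = -1, Rec = 1)),
    rxn("r_phos",   1e-5, c(RecA = 1, STAT3c = 1),  c(STAT3c = -1, STAT3p = 1)),
    rxn("r_dim",    2e-4, c(STAT3p = 2),            c(STAT3p = -2, DimC = 1)),
    rxn("r_imp",    2e-3, c(DimC = 1),              c(DimC = -1, DimN = 1)),
    rxn("r_dephos", 5e-5, c(DimN = 1, PP = 1),      c(DimN = -1, STAT3c = 2)),
    rxn("r_mrna",    2e-4, c(DimN = 1),              c(mRNA = 1)),
    rxn("r_tln",    2e-2, c(mRNA = 1),              c(SOCS = 1)),
    rxn("r_mdeg",   3e-3, c(mRNA = 1),              c(mRNA = -1)),
    rxn("r_sdeg",   1e-3, c(SOCS = 1),              c(SOCS = -1)),
    rxn("r_seq",    1e-5, c(RecA = 1, SOCS = 1),    c(RecA = -1, SOCS = -1, RecA_SOCS = 1)),
    rxn("r_rel",    1e-3, c(RecA_SOCS = 1),         c(RecA_SOCS = -1, RecA = 1, SOCS = 1))
  )
  kinetic_model("demo_steady", init, reactions, stimulus = 10,
                stimulus_name = "IL6", output_names = c("DimN", "SOCS"),
                oscillatory = FALSE, default_horizon_h = 10)
}

#' Reduced NF-kB-style oscillator demo model (two negative feedback loops)
#'
#' A 13-state mass-action reduction of TNF-like NF-kB signalling with its two
#' negative feedback loops (an IkB-style inhibitor and an A20-style kinase
#' regulator). The stimulus activates a preexisting receptor/adapter, which
#' converts preexisting neutral kinase to its active form. Active kinase
#' liberates the transcription factor from a preexisting cytoplasmic
#' inhibitor-factor complex; the free factor enters the nucleus (nuclear
#' factor = the single output) and drives transcription/translation of (i)
#' the inhibitor, which re-sequesters the factor in cytoplasm and nucleus,
#' and (ii) the second regulator, which inactivates the active kinase. mRNAs
#' and proteins decay first-order. Under nominal stimulus the output shows
#' sustained oscillation with at least three complete peak-pairs in 15 h.
#'
#' Preexisting species: receptor/adapter (`TNFR`), neutral kinase (`IKKn`),
#' inhibitor-factor complex (`NIc`). Units: nM and seconds.
#'
#' @return a `kin_model` with output `NFkBn` (nuclear factor).
#' @export
build_demo_oscillator <- function() {
  init <- c(TNFR = 100, TNFRa = 0, IKKn = 200, IKKa = 0, IKKi = 0,
            NIc = 120, NFkBc = 0, NFkBn = 0, IkBc = 0, IkBn = 0,
            mIkB = 0, mA20 = 0, A20 = 0)
  reactions <- list(
    rxn("r_ract",   2e-4, c(TNFR = 1),              c(TNFR = -1, TNFRa = 1), stim = 1),
    rxn("r_rdeact", 1e-3, c(TNFRa = 1),             c(TNFRa = -1, TNFR = 1)),
    rxn("r_ikkact", 4e-5, c(TNFRa = 1, IKKn = 1),   c(IKKn = -1, IKKa = 1)),
    rxn("r_ikka20", 5e-3, c(IKKa = 1, A20 = 1),     c(IKKa = -1, IKKi = 1)),
    rxn("r_ikki",   1.5e-3, c(IKKa = 1),            c(IKKa = -1, IKKi = 1)),
    rxn("r_ikkrec", 3e-3, c(IKKi = 1),              c(IKKi = -1, IKKn = 1)),
    rxn("r_lib",    5e-4, c(IKKa = 1, NIc = 1),     c(NIc = -1, NFkBc = 1)),
    rxn("r_imp",    5e-3, c(NFkBc = 1),             c(NFkBc = -1, NFkBn = 1)),
    rxn("r_mrna_ikb",  5e-6, c(NFkBn = 1),             c(mIkB = 1)),
    rxn("r_mideg",  4e-4, c(mIkB = 1),              c(mIkB = -1)),
    rxn("r_tln_ikb",  0.5,  c(mIkB = 1),              c(IkBc = 1)),
    rxn("r_ideg",   1e-4, c(IkBc = 1),              c(IkBc = -1)),
    rxn("r_ikbikk", 1e-3, c(IkBc = 1, IKKa = 1),    c(IkBc = -1)),
    rxn("r_seqc",   5e-4, c(NFkBc = 1, IkBc = 1),   c(NFkBc = -1, IkBc = -1, NIc = 1)),
    rxn("r_iimp",   1e-3, c(IkBc = 1),              c(IkBc = -1, IkBn = 1)),
    rxn("r_seqn",   5e-4, c(NFkBn = 1, IkBn = 1),   c(NFkBn = -1, IkBn = -1, NIc = 1)),
    rxn("r_mrna_a20",  1e-5, c(NFkBn = 1),             c(mA20 = 1)),
    rxn("r_madeg",  4e-4, c(mA20 = 1),              c(mA20 = -1)),
    rxn("r_tln_a20",  0.5,  c(mA20 = 1),              c(A20 = 1)),
    rxn("r_a20deg", 1e-3, c(A20 = 1),               c(A20 = -1))
  )
  kinetic_model("demo_oscillator", init, reactions, stimulus = 10,
                stimulus_name = "TNF", output_names = "NFkBn",
                oscillatory = TRUE, default_horizon_h = 15)
}
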