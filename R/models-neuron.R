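#' Build a reduced layer-V pyramidal neuron model
#'
#' A two-compartment (somatic + apical) conductance-based neuron with the
#' channel repertoire of detailed layer-V pyramidal cell models: transient
#' and persistent Na, fast delayed-rectifier K, slow (M-type) K, SK
#' (Ca-activated K), high-voltage-activated (L-type) Ca,
#' low-voltage-activated (T-type) Ca, HCN (I_h, concentrated apically),
#' and leak, plus a somatic Ca pool whose clearance rate is the SERCA-like
#' uptake parameter `P_up`.  The reduced morphology stands in for full
#' multicompartmental reconstructions; neuron-side claims made with it are
#' directional (signs, monotonicity), not absolute.
#'
#' The SK coupling gives the model its signature Ca-channel gain reversal:
#' more Ca influx raises intracellular Ca, activates SK, and *lowers* the
#' firing rate, opposite to the direct depolarising effect of Ca currents.
#'
#' @param variant Only `"reduced"` is provided.
#' @return A [cell_model()] that is quiescent at rest and fires
#'   repetitively under suprathreshold somatic DC.
#' @export
build_neuron <- function(variant = c("reduced")) {
  variant <- match.arg(variant)
  p <- .neuron_reduced_params()
  layout <- model_parameter_layout("neuron")
  stopifnot(setequal(names(p), layout))
  p <- p[layout]
  s0 <- c(Vs = -75, Vd = -75, m = 0.01, h = 0.8, pp = 0.01, n = 0.01,
          u = 0.01, z = 0, c = 0.01, hc = 0.7, s = 0.01, hs = 0.3,
          q = 0.2, Cai = 1e-4)
  s0 <- s0[model_state_layout("neuron")]
  cell_model(name = "neuron-reduced", family = "neuron",
             params = p, state0 = s0,
             provenance = paste0(
               "reduced two-compartment cortical layer-V pyramidal neuron ",
               "with the standard detailed-model channel repertoire ",
               "(Na_t/Na_p, fast+slow K, SK, L- and T-type Ca, HCN, leak)"))
}

.neuron_reduced_params <- function() {
  c(Cs = 0.25, Cd = 0.5, gc = 0.05,
    gNaT = 20, vm = -38, km = 6, taum = 1, vh = -60, kh = 6, tauh = 1,
    gNaP = 0.01, vp = -52, kp = 4.6, taup = 1,
    gKdr = 7, vn = -25, kn = 9, taun = 1,
    gKM = 0.03, vu = -35, ku = 6, tauu = 100,
    gSK = 0.1, KSK = 0.0005, tauz = 5,
    gCaHVA = 0.015, vc = -20, kc = 6, tauc = 1.5,
    vhc = -45, khc = 11, tauhc = 50,
    gCaLVA = 0.006, vs = -50, ks = 6.5, taus = 3,
    vhs = -70, khs = 5, tauhs = 40,
    gH = 0.004, vq = -78, kq = 7, tauq = 200, Eh = -45, gHd = 0.008,
    gLs = 0.01, gLd = 0.015, EL = -80,
    alphaCa = 0.0002, Pup = 0.02, Ca0 = 1e-4,
    ECa = 120, EK = -85, ENa = 60)
}
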