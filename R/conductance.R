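# Excitatory/inhibitory conductance decomposition from voltage-clamp
# currents recorded at the two reversal potentials. Holding at the
# inhibitory (chloride) reversal isolates the excitatory current and vice
# versa:
#   I(E_inh) = g_exc * (E_inh - E_exc)  ->  g_exc = I(E_inh) / (E_inh - E_exc)
#   I(E_exc) = g_inh * (E_exc - E_inh)  ->  g_inh = I(E_exc) / (E_exc - E_inh)
# with currents in pA and potentials in mV, conductances come out in nS.

#' Decompose clamp currents into excitatory and inhibitory conductances
#'
#' @param I_at_Einh Current trace (pA) recorded holding at the inhibitory
#'   reversal potential (isolates excitation); baseline-subtracted.
#' @param I_at_Eexc Current trace (pA) recorded holding at the excitatory
#'   reversal potential (isolates inhibition); same length.
#' @param E_exc_mV Excitatory (cation) reversal potential, default 0 mV.
#' @param E_inh_mV Inhibitory (chloride) reversal potential, default
#'   -68.5 mV.
#' @param dt_s Sample interval (s), carried through for downstream kinetics.
#' @param neg_tolerance_nS Conductance excursions below
#'   `-neg_tolerance_nS` trigger a warning (small negative noise excursions
#'   are expected; large ones indicate wrong reversal settings). Default
#'   0.5 nS.
#' @return An object of class `conductance_pair`: list with `g_exc`, `g_inh`
#'   (nS), `E_exc_mV`, `E_inh_mV`, `dt_s`.
#' @export
decompose_conductances <- function(I_at_Einh, I_at_Eexc, E_exc_mV = 0,
                                   E_inh_mV = -68.5, dt_s = 1e-3,
                                   neg_tolerance_nS = 0.5) {
  I_at_Einh <- as.numeric(I_at_Einh)
  I_at_Eexc <- as.numeric(I_at_Eexc)
  check_numeric_vector(I_at_Einh, "I_at_Einh")
  check_numeric_vector(I_at_Eexc, "I_at_Eexc")
  if (length(I_at_Einh) != length(I_at_Eexc)) {
    stop_param("I_at_Eexc", "current traces must have equal length")
  }
  check_scalar(E_exc_mV, "E_exc_mV")
  check_scalar(E_inh_mV, "E_inh_mV")
  if (E_exc_mV == E_inh_mV) {
    stop_param("E_inh_mV", "reversal potentials must differ")
  }
  if (E_exc_mV < E_inh_mV) {
    stop_param("E_exc_mV", "excitatory reversal must exceed inhibitory reversal")
  }
  check_scalar(dt_s, "dt_s", positive = TRUE)

  g_exc <- I_at_Einh / (E_inh_mV - E_exc_mV)   # pA / mV = nS
  g_inh <- I_at_Eexc / (E_exc_mV - E_inh_mV)
  n_neg <- sum(g_exc < -neg_tolerance_nS) + sum(g_inh < -neg_tolerance_nS)
  if (n_neg > 0) {
    warning(sprintf(
      "%d conductance samples below -%g nS; check reversal-potential settings",
      n_neg, neg_tolerance_nS), call. = FALSE)
  }
  structure(list(g_exc = g_exc, g_inh = g_inh, E_exc_mV = E_exc_mV,
                 E_inh_mV = E_inh_mV, dt_s = dt_s),
            class = "conductance_pair")
}

#' Peak excitatory/inhibitory conductance ratio
#'
#' Ratio of the largest excitatory conductance to the largest inhibitory
#' conductance over the recording; the two maxima need not be simultaneous.
#' Computed on trial-averaged conductances when repeats are available.
#'
#' @param pair A [conductance_pair][decompose_conductances()].
#' @return Dimensionless ratio `max g_exc / max g_inh`.
#' @export
peak_conductance_ratio <- function(pair) {
  stopifnot(inherits(pair, "conductance_pair"))
  pk_inh <- max(pair$g_inh)
  if (pk_inh <= 0) {
    stop("undefined ratio: peak inhibitory conductance is not positive",
         call. = FALSE)
  }
  max(pair$g_exc) / pk_inh
}
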