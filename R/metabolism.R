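# Local growth-rate law and metabolite source terms.
#
# Three growth modes are combined into one local biomass growth rate
#   lambda = lambda1 * theta_o + lambda2 * (1 - theta_o) + lambda3 * (1 - theta_g) * theta_o
# where lambda1/lambda2/lambda3 are the (maintenance-shifted) Monod rates for
# aerobic growth on glucose, anaerobic growth on glucose, and aerobic growth on
# acetate, and the theta weights encode the oxygen state and the hierarchical
# preference of glucose over acetate.
#
# Carbon bookkeeping is done in carbon-atom units: 1 mmol glucose = 6 mmol C,
# 1 mmol acetate = 2 mmol C. The maintenance requirement m_carbon is a carbon
# flux (mmol C/gdw/h).

CARBON_GLUCOSE <- 6
CARBON_ACETATE <- 2

#' Monod saturation fraction
#'
#' @param C substrate concentration, mM (vectorised, all >= 0).
#' @param K Monod (half-saturation) constant, mM (> 0).
#' @return `C / (C + K)`, in `[0, 1)` and monotone increasing in `C`.
#' @examples
#' monod(1, 1)   # 0.5 at half-saturation
#' @export
monod <- function(C, K) {
  if (any(C < 0)) stop("concentration must be >= 0")
  if (any(K <= 0)) stop("Monod constant must be > 0")
  C / (C + K)
}

#' Maintenance concentration threshold
#'
#' The substrate concentration `C*` at which Monod-limited uptake at maximal
#' capacity exactly covers the maintenance flux: solving
#' `q_max * C / (C + K) = m` gives `C* = K * m / (q_max - m)`. Below `C*` a
#' cell cannot both cover maintenance and grow in that mode.
#'
#' @param q_max maximal uptake flux of the substrate (same units as `m`).
#' @param m maintenance flux requirement (>= 0, < `q_max`).
#' @param K Monod constant of the uptake kinetics, mM.
#' @return threshold concentration `C*` in mM; 0 when `m = 0`.
#' @export
maintenance_threshold <- function(q_max, m, K) {
  if (any(m < 0)) stop("maintenance flux must be >= 0")
  if (any(K <= 0)) stop("Monod constant must be > 0")
  if (any(m >= q_max))
    stop("maintenance flux m >= uptake capacity q_max: ",
         "maintenance unreachable at any concentration")
  K * m / (q_max - m)
}

#' Maintenance-shifted Monod growth rate
#'
#' Growth in a mode is zero at or below the mode's maintenance threshold `C*`;
#' above it the Monod curve is shifted so that it starts from `C*`:
#' `lambda_max * (C - C*) / ((C - C*) + K)`. The form is continuous at
#' `C = C*` and reduces to the plain Monod law when `C* = 0`.
#'
#' @param lambda_max maximal growth rate of the mode, 1/h.
#' @param C substrate concentration, mM (vectorised).
#' @param K Monod constant, mM.
#' @param C_star maintenance threshold from [maintenance_threshold()], mM.
#' @return growth rate, 1/h.
#' @export
shifted_monod_rate <- function(lambda_max, C, K, C_star) {
  if (any(C < 0) || any(C_star < 0) || lambda_max < 0)
    stop("inputs must be nonnegative")
  if (any(K <= 0)) stop("Monod constant must be > 0")
  s <- pmax(C - C_star, 0)
  lambda_max * s / (s + K)
}

# Mode-specific maintenance thresholds (glucose aerobic / glucose anaerobic /
# acetate aerobic), each assuming maintenance borne entirely by that substrate.
# A mode whose capacity cannot cover maintenance gets an infinite threshold
# (the mode never contributes growth).
growth_thresholds <- function(p) {
  m_g <- p$m_carbon / CARBON_GLUCOSE   # glucose-equivalent maintenance flux
  m_a <- p$m_carbon / CARBON_ACETATE   # acetate-equivalent maintenance flux
  thr <- function(q_max, m, K) {
    if (m >= q_max) Inf else maintenance_threshold(q_max, m, K)
  }
  list(
    g_aer = thr(p$q_g_aer * p$lambda_g_aer, m_g, p$K_g),
    g_ana = thr(p$q_g_ana * p$lambda_g_ana, m_g, p$K_g),
    a_aer = thr(p$q_a_aer * p$lambda_a_aer, m_a, p$K_a)
  )
}

#' Local growth rate from metabolite concentrations
#'
#' Evaluates the three-mode weighted growth law at given local glucose, oxygen
#' and acetate concentrations (vectorised over grid points or cells). The mode
#' rates use the maintenance-shifted Monod form; the weights use the raw Monod
#' fractions.
#'
#' @param C_g,C_o,C_a concentrations, mM (equal-length vectors).
#' @param p a [colony_params()] set.
#' @return list of class `growth_rates` with elements `lambda_total`,
#'   `lambda1`, `lambda2`, `lambda3` (1/h) and `theta_g`, `theta_o`, `theta_a`.
#' @export
local_growth_rate <- function(C_g, C_o, C_a, p) {
  theta_g <- monod(C_g, p$K_g)
  theta_o <- monod(C_o, p$K_o)
  theta_a <- monod(C_a, p$K_a)
  thr <- growth_thresholds(p)
  lam1 <- if (is.finite(thr$g_aer))
    shifted_monod_rate(p$lambda_g_aer, C_g, p$K_g, thr$g_aer) else 0 * C_g
  lam2 <- if (is.finite(thr$g_ana))
    shifted_monod_rate(p$lambda_g_ana, C_g, p$K_g, thr$g_ana) else 0 * C_g
  lam3 <- if (is.finite(thr$a_aer))
    shifted_monod_rate(p$lambda_a_aer, C_a, p$K_a, thr$a_aer) else 0 * C_a
  total <- lam1 * theta_o + lam2 * (1 - theta_o) + lam3 * (1 - theta_g) * theta_o
  structure(list(lambda_total = total, lambda1 = lam1, lambda2 = lam2,
                 lambda3 = lam3, theta_g = theta_g, theta_o = theta_o,
                 theta_a = theta_a),
            class = "growth_rates")
}

#' Maintenance carbon allocation and starvation state
#'
#' Computes the carbon flux a cell can achieve at the local concentrations
#' (glucose in either oxygen state, acetate only when oxygen is present and
#' glucose is depleted, via the `(1 - theta_g) * theta_o` gate), allocates it
#' to maintenance first — glucose before acetate, reflecting the hierarchical
#' substrate preference — and classifies the cell as starving when the
#' achievable carbon uptake falls short of the maintenance requirement.
#' Maintenance glucose consumed anaerobically is fermented and excretes
#' `acetate_per_glucose_maint` mol acetate per mol glucose.
#'
#' @inheritParams local_growth_rate
#' @return list with maintenance source components (`Q_g_maint`, `Q_o_maint`,
#'   `Q_a_maint` uptakes and `P_a_maint` excretion, mmol/gdw/h), the achievable
#'   carbon flux `carbon_flux` (mmol C/gdw/h), and logical vectors `starving`
#'   and `anaerobic` (local oxygen below the anoxia cutoff).
#' @export
maintenance_allocation <- function(C_g, C_o, C_a, p) {
  theta_g <- monod(C_g, p$K_g)
  theta_o <- monod(C_o, p$K_o)
  theta_a <- monod(C_a, p$K_a)
  # uptake capacities, substrate units (mmol substrate/gdw/h)
  U_g <- (p$q_g_aer * p$lambda_g_aer * theta_o +
            p$q_g_ana * p$lambda_g_ana * (1 - theta_o)) * theta_g
  U_a <- p$q_a_aer * p$lambda_a_aer * theta_a * (1 - theta_g) * theta_o
  carbon <- CARBON_GLUCOSE * U_g + CARBON_ACETATE * U_a
  starving <- carbon < p$m_carbon
  maint_g_c <- pmin(CARBON_GLUCOSE * U_g, p$m_carbon)
  maint_a_c <- pmin(CARBON_ACETATE * U_a, p$m_carbon - maint_g_c)
  Q_g_maint <- maint_g_c / CARBON_GLUCOSE
  Q_a_maint <- maint_a_c / CARBON_ACETATE
  P_a_maint <- p$acetate_per_glucose_maint * Q_g_maint * (1 - theta_o)
  # oxygen for the aerobically respired maintenance carbon (full oxidation:
  # 6 O2 per glucose, 2 O2 per acetate)
  Q_o_maint <- CARBON_GLUCOSE * Q_g_maint * theta_o + CARBON_ACETATE * Q_a_maint
  list(Q_g_maint = Q_g_maint, Q_o_maint = Q_o_maint, Q_a_maint = Q_a_maint,
       P_a_maint = P_a_maint, carbon_flux = carbon, starving = starving,
       anaerobic = C_o < p$anoxia_cutoff_factor * p$K_o)
}

#' Metabolite uptake and excretion rates
#'
#' Assembles the per-biomass source rates that drive the reaction-diffusion
#' equations: glucose and oxygen are only consumed (`P_g = P_o = 0`), acetate
#' is excreted by growth on glucose (fermentation, plus a small aerobic
#' overflow component) and consumed by aerobic growth on acetate; maintenance
#' components are added on top of the growth-coupled terms.
#'
#' @param g a `growth_rates` object from [local_growth_rate()].
#' @param maint maintenance components from [maintenance_allocation()].
#' @param p a [colony_params()] set.
#' @return list of class `source_terms` with uptakes `Q_g`, `Q_o`, `Q_a` and
#'   excretion `P_a` (mmol/gdw/h; `P_g` and `P_o` identically zero), plus the
#'   flux components used by [flux_partition()].
#' @export
source_terms <- function(g, maint, p) {
  Q_g_growth_aer <- p$q_g_aer * g$lambda1 * g$theta_o
  Q_g_growth_ana <- p$q_g_ana * g$lambda2 * (1 - g$theta_o)
  Q_a_growth <- p$q_a_aer * g$lambda3 * (1 - g$theta_g) * g$theta_o
  Q_g <- Q_g_growth_aer + Q_g_growth_ana + maint$Q_g_maint
  Q_o <- p$q_o_g * g$lambda1 * g$theta_o +
    p$q_o_a * g$lambda3 * (1 - g$theta_g) * g$theta_o + maint$Q_o_maint
  P_a <- p$p_a_aer * g$lambda1 * g$theta_o +
    p$p_a_ana * g$lambda2 * (1 - g$theta_o) + maint$P_a_maint
  Q_a <- Q_a_growth + maint$Q_a_maint
  structure(list(
    Q_g = Q_g, Q_o = Q_o, Q_a = Q_a, P_a = P_a,
    P_g = 0 * Q_g, P_o = 0 * Q_g,
    Q_g_maint = maint$Q_g_maint, Q_o_maint = maint$Q_o_maint,
    Q_a_maint = maint$Q_a_maint, P_a_maint = maint$P_a_maint,
    # partition components: aerobic/anaerobic glucose, growth/maintenance acetate
    Q_g_aer = Q_g_growth_aer + maint$Q_g_maint * g$theta_o,
    Q_g_ana = Q_g_growth_ana + maint$Q_g_maint * (1 - g$theta_o),
    Q_a_growth = Q_a_growth
  ), class = "source_terms")
}

#' Stoichiometric upper bound on excreted acetate
#'
#' Fermentation of one glucose yields at most two acetate, so the acetate
#' concentration that a colony can ever excrete is bounded by twice the
#' initial glucose concentration.
#'
#' @param C_g_init initial glucose concentration in the agar, mM.
#' @return maximal acetate concentration, mM (`2 * C_g_init`).
#' @examples
#' acetate_yield_bound(20)  # 40 mM
#' @export
acetate_yield_bound <- function(C_g_init) {
  if (any(C_g_init < 0)) stop("initial glucose must be >= 0")
  2 * C_g_init
}
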