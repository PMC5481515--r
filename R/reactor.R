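#' Reactor configuration for a two-compartment STR-PFR system
#'
#' Bundles the physical parameters of a scale-down chemostat consisting of a
#' stirred tank reactor (STR, the well-mixed nutrient-limited zone) coupled to
#' a plug-flow reactor (PFR, the starvation zone) through a recycle loop.
#' Defaults describe a 1.12 l STR with a 0.38 l PFR (1:3 PFR:STR volume
#' ratio), a recycle flow giving a PFR residence time of 125 s, a dilution
#' rate of 0.2 1/h, an ammonia uptake rate of 56 ug/l/s and a residual
#' ammonia concentration of 2.5 mg/l entering the loop.
#'
#' @param V_str STR volume (l).
#' @param V_pfr PFR volume (l).
#' @param recycle_flow volumetric recycle flow through the PFR loop (l/s).
#' @param D dilution rate (1/h).
#' @param mu_avg average specific growth rate of the whole system (1/h);
#'   equals `D` at steady state.
#' @param q_substrate volumetric substrate uptake rate (mg/l/s).
#' @param c_detect residual substrate concentration entering the loop (mg/l).
#' @param port_times named numeric vector of PFR sample-port residence times
#'   (s), strictly increasing in port order.
#' @param loop_in,loop_out residence times (s) of the connecting loop before
#'   the first and after the last port; the total PFR residence time is
#'   `max(port_times) + loop_out`.
#' @return An object of class `reactor_config`.
#' @examples
#' cfg <- reactor_config()
#' reactor_summary(cfg)
#' @export
reactor_config <- function(V_str = 1.12, V_pfr = 0.38,
                           recycle_flow = 3.04e-3,
                           D = 0.2, mu_avg = 0.2,
                           q_substrate = 0.056, c_detect = 2.5,
                           port_times = c(P1 = 30, P2 = 50, P3 = 70,
                                          P4 = 90, P5 = 110),
                           loop_in = 0, loop_out = 15) {
  check_positive(V_str, "V_str"); check_positive(V_pfr, "V_pfr")
  check_positive(recycle_flow, "recycle_flow")
  check_positive(D, "D"); check_positive(mu_avg, "mu_avg")
  check_positive(q_substrate, "q_substrate")
  check_positive(c_detect, "c_detect")
  check_positive(port_times, "port_times")
  check_nonneg(loop_in, "loop_in"); check_nonneg(loop_out, "loop_out")
  if (is.null(names(port_times)) || any(!nzchar(names(port_times))))
    stopf("`port_times` must be a named vector")
  if (any(diff(port_times) <= 0))
    stopf("`port_times` must be strictly increasing in port order")
  structure(list(V_str = V_str, V_pfr = V_pfr, recycle_flow = recycle_flow,
                 D = D, mu_avg = mu_avg, q_substrate = q_substrate,
                 c_detect = c_detect, port_times = port_times,
                 loop_in = loop_in, loop_out = loop_out),
            class = "reactor_config")
}

#' Read a reactor configuration from YAML or JSON
#'
#' Expects the keys `V_str_l, V_pfr_l, recycle_flow_l_per_s, D_per_h,
#' mu_avg_per_h, q_substrate_mg_per_l_s, c_detect_mg_per_l, port_times_s,
#' loop_in_s, loop_out_s`.
#'
#' @param path file path; format chosen by extension (`.json` vs `.yaml`/`.yml`).
#' @return A [reactor_config()] object.
#' @export
read_reactor_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  need <- c("V_str_l", "V_pfr_l", "recycle_flow_l_per_s", "D_per_h",
            "mu_avg_per_h", "q_substrate_mg_per_l_s", "c_detect_mg_per_l",
            "port_times_s", "loop_in_s", "loop_out_s")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stopf("reactor config is missing keys: %s",
                          paste(miss, collapse = ", "))
  reactor_config(V_str = raw$V_str_l, V_pfr = raw$V_pfr_l,
                 recycle_flow = raw$recycle_flow_l_per_s,
                 D = raw$D_per_h, mu_avg = raw$mu_avg_per_h,
                 q_substrate = raw$q_substrate_mg_per_l_s,
                 c_detect = raw$c_detect_mg_per_l,
                 port_times = unlist(raw$port_times_s),
                 loop_in = raw$loop_in_s, loop_out = raw$loop_out_s)
}

#' Mean hydraulic residence time of a compartment
#'
#' @param V compartment volume (l).
#' @param F_flow volumetric flow through the compartment (l/s).
#' @return Residence time `V / F_flow` in seconds.
#' @examples
#' mean_residence_time(0.38, 3.04e-3)  # ~125 s
#' @export
mean_residence_time <- function(V, F_flow) {
  check_positive(V, "V"); check_positive(F_flow, "F_flow")
  V / F_flow
}

#' Total PFR residence time implied by a configuration
#'
#' Last sample port plus the outlet loop.
#' @param cfg a [reactor_config()].
#' @return seconds.
#' @export
tau_pfr_total <- function(cfg) {
  stopifnot(inherits(cfg, "reactor_config"))
  max(cfg$port_times) + cfg$loop_out
}

#' Substrate depletion time under zero-order consumption
#'
#' Time for the residual substrate entering the plug-flow loop to be fully
#' consumed at a constant volumetric uptake rate, `c_detect / q_substrate`.
#' Fluid elements beyond this residence time are in the starvation zone.
#'
#' @param c_detect residual substrate concentration entering the loop (mg/l).
#' @param q_substrate volumetric uptake rate (mg/l/s).
#' @return Depletion time in seconds.
#' @examples
#' depletion_time(2.5, 0.056)  # ~45 s
#' @export
depletion_time <- function(c_detect, q_substrate) {
  check_positive(c_detect, "c_detect")
  check_positive(q_substrate, "q_substrate")
  c_detect / q_substrate
}

#' Effective growth rate in the substrate-containing growth zone
#'
#' With growth confined to the volume that still contains substrate (the STR
#' plus the PFR section up to the depletion time) and biomass distributed
#' uniformly, the whole-system average rate `mu_avg` concentrates into the
#' growth zone: `mu = mu_avg * (V_str + V_pfr) / V_growth`, where plug flow
#' makes axial volume proportional to residence time, so
#' `V_growth = V_str + V_pfr * t_deplete / tau_pfr_total`.
#'
#' @param mu_avg whole-system average specific growth rate (1/h).
#' @param cfg a [reactor_config()].
#' @param t_deplete substrate depletion time (s); must not exceed the total
#'   PFR residence time.
#' @return Growth-zone specific growth rate (1/h).
#' @examples
#' cfg <- reactor_config()
#' effective_growth_rate(0.2, cfg, depletion_time(2.5, 0.056))  # ~0.24
#' @export
effective_growth_rate <- function(mu_avg, cfg, t_deplete) {
  stopifnot(inherits(cfg, "reactor_config"))
  check_positive(mu_avg, "mu_avg"); check_positive(t_deplete, "t_deplete")
  tau_tot <- tau_pfr_total(cfg)
  if (t_deplete > tau_tot)
    stopf("t_deplete (%.1f s) exceeds the total PFR residence time (%.1f s)",
          t_deplete, tau_tot)
  V_growth <- cfg$V_str + cfg$V_pfr * t_deplete / tau_tot
  mu_avg * (cfg$V_str + cfg$V_pfr) / V_growth
}

#' Fold changes of a metabolite profile along the PFR relative to the STR
#'
#' @param port_values concentrations at the PFR sample ports (same units as
#'   `baseline`), non-negative.
#' @param baseline STR (inlet) concentration, strictly positive.
#' @return A list with `fold` (per-port value/baseline) and `mean_fold`.
#' @examples
#' profile_fold_change(c(1, 1.5, 2), baseline = 0.5)
#' @export
profile_fold_change <- function(port_values, baseline) {
  check_positive(baseline, "baseline")
  check_nonneg(port_values, "port_values")
  fold <- port_values / baseline
  list(fold = fold, mean_fold = mean(fold))
}

#' Physical summary of an STR-PFR configuration
#'
#' @param cfg a [reactor_config()].
#' @return A list with compartment residence times, total volume, STR volume
#'   fraction, depletion time, growth-zone length and effective growth rate.
#' @export
reactor_summary <- function(cfg) {
  stopifnot(inherits(cfg, "reactor_config"))
  t_dep <- depletion_time(cfg$c_detect, cfg$q_substrate)
  tau_tot <- tau_pfr_total(cfg)
  out <- list(
    tau_str_s = mean_residence_time(cfg$V_str, cfg$recycle_flow),
    tau_pfr_s = tau_tot,
    cycle_time_s = mean_residence_time(cfg$V_str, cfg$recycle_flow) + tau_tot,
    V_total_l = cfg$V_str + cfg$V_pfr,
    str_volume_fraction = cfg$V_str / (cfg$V_str + cfg$V_pfr),
    depletion_time_s = min(t_dep, tau_tot),
    mu_growth_zone = effective_growth_rate(cfg$mu_avg, cfg, min(t_dep, tau_tot)))
  class(out) <- "reactor_summary"
  out
}

#' @export
print.reactor_summary <- function(x, ...) {
  cat("STR-PFR system summary\n")
  cat(sprintf("  tau_STR            %8.1f s\n", x$tau_str_s))
  cat(sprintf("  tau_PFR (total)    %8.1f s\n", x$tau_pfr_s))
  cat(sprintf("  cycle time         %8.1f s\n", x$cycle_time_s))
  cat(sprintf("  STR volume share   %8.1f %%\n", 100 * x$str_volume_fraction))
  cat(sprintf("  depletion time     %8.1f s\n", x$depletion_time_s))
  cat(sprintf("  mu (growth zone)   %8.3f 1/h\n", x$mu_growth_zone))
  invisible(x)
}

#' @export
print.reactor_config <- function(x, ...) {
  cat(sprintf("reactor_config: V_str %.2f l, V_pfr %.2f l, flow %.3g l/s, D %.2f 1/h\n",
              x$V_str, x$V_pfr, x$recycle_flow, x$D))
  cat(sprintf("  ports: %s (s), outlet loop %.0f s\n",
              paste(sprintf("%s=%g", names(x$port_times), x$port_times),
                    collapse = " "), x$loop_out))
  invisible(x)
}
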