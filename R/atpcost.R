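#' ATP cost model for transcriptional switching
#'
#' Coefficients for estimating the ATP expenditure of repeatedly switching
#' genes on and off as cells cycle between the nutrient-limited stirred
#' tank and the starvation loop. Polymerization costs only: about 2 ATP
#' equivalents per transcribed nucleotide and 4.3 per polymerized amino
#' acid; an induced transcript is assumed to be translated
#' `proteins_per_mrna_cycle` times within one cycle. The per-cell mRNA pool
#' converts TPM shifts into absolute transcript copies, and the non-growth
#' maintenance coefficient `m_atp` sets the reference demand that switching
#' costs are expressed against.
#'
#' @param c_nt ATP equivalents per transcribed nucleotide.
#' @param c_aa ATP equivalents per polymerized amino acid.
#' @param mrna_pool mRNA molecules per cell.
#' @param proteins_per_mrna_cycle translation burst per induced transcript
#'   per cycle.
#' @param m_atp non-growth maintenance (mmol ATP / gDW / h).
#' @param cycle_time STR + PFR circulation time (s).
#' @param cells_per_gdw cells per gram dry weight.
#' @return A `cost_model` list; cycle frequency (1/h) is derived as
#'   `3600 / cycle_time`.
#' @export
cost_model <- function(c_nt = 2.0, c_aa = 4.3, mrna_pool = 1380,
                       proteins_per_mrna_cycle = 10, m_atp = 3.3,
                       cycle_time = 497, cells_per_gdw = 1e12) {
  for (nm in c("c_nt", "c_aa", "mrna_pool", "proteins_per_mrna_cycle",
               "m_atp", "cycle_time", "cells_per_gdw"))
    check_positive(get(nm), nm)
  structure(list(c_nt = c_nt, c_aa = c_aa, mrna_pool = mrna_pool,
                 proteins_per_mrna_cycle = proteins_per_mrna_cycle,
                 m_atp = m_atp, cycle_time = cycle_time,
                 cells_per_gdw = cells_per_gdw,
                 cycles_per_h = 3600 / cycle_time),
            class = "cost_model")
}

#' Read a cost model from YAML
#'
#' Keys matching the [cost_model()] arguments; missing keys keep defaults.
#' @param path YAML file.
#' @return A `cost_model`.
#' @export
read_cost_model <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(cost_model, raw[intersect(names(raw), names(formals(cost_model)))])
}

#' Transcript copies switched on per cell per cycle
#'
#' Converts the TPM shift between the stirred tank and the loop outlet into
#' newly synthesized mRNA copies per cell. Only induction costs ATP (decay
#' of down-regulated transcripts is free), so down-shifts map to zero.
#'
#' @param tpm_str,tpm_pfr per-gene TPM in the STR and at the PFR outlet.
#' @param mrna_pool mRNA molecules per cell.
#' @return `pmax(0, (tpm_pfr - tpm_str)) / 1e6 * mrna_pool`.
#' @examples
#' delta_copies(100, 600, 1380)  # 0.69 copies per cell per cycle
#' @export
delta_copies <- function(tpm_str, tpm_pfr, mrna_pool = 1380) {
  check_nonneg(tpm_str, "tpm_str"); check_nonneg(tpm_pfr, "tpm_pfr")
  check_positive(mrna_pool, "mrna_pool")
  pmax(0, tpm_pfr - tpm_str) / 1e6 * mrna_pool
}

#' Per-gene ATP cost of one switching cycle
#'
#' Transcription cost `delta_mrna * length_nt * c_nt` plus translation cost
#' `delta_mrna * proteins_per_mrna_cycle * length_aa * c_aa`, in ATP
#' equivalents per cell per cycle.
#'
#' @param genes a `gene_table` (needs `gene_id`, `length_nt`, `length_aa`).
#' @param delta_mrna per-gene switched transcript copies
#'   (see [delta_copies()]).
#' @param model a [cost_model()].
#' @return A `gene_cost` data frame: `gene_id`, `delta_mrna`,
#'   `atp_transcription`, `atp_translation`, `atp_total`.
#' @export
gene_switch_cost <- function(genes, delta_mrna, model = cost_model()) {
  stopifnot(inherits(model, "cost_model"))
  if (length(delta_mrna) != nrow(genes))
    stopf("`delta_mrna` must have one entry per gene")
  check_nonneg(delta_mrna, "delta_mrna")
  atp_tx <- delta_mrna * genes$length_nt * model$c_nt
  atp_tl <- delta_mrna * model$proteins_per_mrna_cycle *
    genes$length_aa * model$c_aa
  structure(data.frame(gene_id = genes$gene_id, delta_mrna = delta_mrna,
                       atp_transcription = atp_tx, atp_translation = atp_tl,
                       atp_total = atp_tx + atp_tl,
                       stringsAsFactors = FALSE),
            class = c("gene_cost", "data.frame"))
}

#' Switching cost as a percentage of maintenance energy
#'
#' Sums the per-gene ATP costs over one cycle, converts to a molar flux per
#' gram dry weight and hour (`sum * cycles_per_h * cells_per_gdw / N_A`, in
#' mmol ATP / gDW / h) and expresses it relative to the non-growth
#' maintenance coefficient.
#'
#' @param costs a [gene_switch_cost()] result.
#' @param model a [cost_model()].
#' @return A `maintenance_cost` list: `percent_of_maintenance`,
#'   `flux_mmol_per_gdw_h`, `atp_per_cell_cycle`, and `table` (genes ranked
#'   by total cost).
#' @export
maintenance_increase <- function(costs, model = cost_model()) {
  stopifnot(inherits(costs, "gene_cost"), inherits(model, "cost_model"))
  avogadro <- 6.02214076e23
  total_atp <- sum(costs$atp_total)
  flux_mol <- total_atp * model$cycles_per_h * model$cells_per_gdw / avogadro
  flux_mmol <- flux_mol * 1e3
  structure(list(percent_of_maintenance = 100 * flux_mmol / model$m_atp,
                 flux_mmol_per_gdw_h = flux_mmol,
                 atp_per_cell_cycle = total_atp,
                 table = costs[order(-costs$atp_total), ]),
            class = "maintenance_cost")
}

#' @export
print.maintenance_cost <- function(x, ...) {
  cat(sprintf("switching cost: %.3g ATP/cell/cycle = %.4f mmol/gDW/h = %.2f%% of maintenance\n",
              x$atp_per_cell_cycle, x$flux_mmol_per_gdw_h,
              x$percent_of_maintenance))
  invisible(x)
}

#' End-to-end switching cost from a TPM matrix
#'
#' Averages TPM over the STR and PFR sample groups, converts the induced
#' shift into switched transcript copies and returns the maintenance
#' summary together with the ranked per-gene cost table.
#'
#' @param tpm_mat TPM matrix (genes x samples, rownames = gene ids).
#' @param str_samples,pfr_samples column names of the two groups.
#' @param genes a `gene_table` matching the rows.
#' @param model a [cost_model()].
#' @return A `maintenance_cost` (see [maintenance_increase()]).
#' @export
atp_switching_cost <- function(tpm_mat, str_samples, pfr_samples, genes,
                               model = cost_model()) {
  stopifnot(all(str_samples %in% colnames(tpm_mat)),
            all(pfr_samples %in% colnames(tpm_mat)),
            nrow(tpm_mat) == nrow(genes))
  tpm_str <- rowMeans(tpm_mat[, str_samples, drop = FALSE])
  tpm_pfr <- rowMeans(tpm_mat[, pfr_samples, drop = FALSE])
  dm <- delta_copies(tpm_str, tpm_pfr, model$mrna_pool)
  maintenance_increase(gene_switch_cost(genes, dm, model), model)
}
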