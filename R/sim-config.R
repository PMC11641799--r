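#' Simulation configuration for the multi-generation stress design
#'
#' Builds the configuration object consumed by [simulate_counts()] and
#' [simulate_traits()]. The simulated design mirrors a four-stage clonal
#' propagation experiment: a stressed generation (P1, groups CK and S), two
#' recovery generations cultivated under control conditions (P1S-P2CK,
#' P1S-P3CK, descendants of the stressed lineage) and a re-exposed generation
#' (P1S-P4S). Five groups are sequenced, each with `n_reps` replicates.
#'
#' Planted gene classes define the ground truth used downstream:
#' \describe{
#'   \item{tmg3_up / tmg3_down}{log2 effect active in all four contrast
#'     groups; multipliers `1, attenuation["P2"], attenuation["P3"],
#'     attenuation["P4"]` on `base_lfc`.}
#'   \item{tmg2_only_up / tmg2_only_down}{as tmg3 but the P3 multiplier is 0,
#'     so the memory fades before the third generation.}
#'   \item{transient}{effect only in the stressed P1 group (S); signs
#'     alternate up/down across the class.}
#'   \item{fluctuating}{effect in every group but with alternating sign
#'     (+, -, +, -), so direction never persists.}
#'   \item{null}{no effect; all genes not covered by `class_counts`.}
#' }
#'
#' @param n_genes total number of genes.
#' @param n_reps replicates per sequenced group.
#' @param class_counts named integer vector of planted class sizes; allowed
#'   names: `tmg3_up`, `tmg3_down`, `tmg2_only_up`, `tmg2_only_down`,
#'   `transient`, `fluctuating`. The remainder up to `n_genes` is the null
#'   class.
#' @param base_lfc log2 fold change planted in the P1 stress group.
#' @param attenuation named multipliers on `base_lfc` for the P2, P3 and P4
#'   contrast groups. The default P4 multiplier (1.2) exceeds 1 so that
#'   memory-carrying genes respond more strongly on re-exposure.
#' @param dispersion_range interval for per-gene NB dispersions, drawn
#'   log-uniformly. Variance model: `v = m + phi * m^2`.
#' @param libsize_range interval for per-sample library-size factors (uniform).
#' @param baseline_range interval for per-gene baseline mean counts, drawn
#'   log-uniformly.
#' @param n_traits_weaken,n_traits_strengthen,n_traits_null numbers of planted
#'   traits of each reaction-norm type.
#' @param trait_reps replicates per trait group (default 6, a typical
#'   phenotyping replication level).
#' @param trait_baseline,trait_effect baseline trait value and absolute effect
#'   of stress on the trait mean (same arbitrary units).
#' @param trait_noise_frac replicate noise SD as a fraction of `trait_effect`.
#' @param seed integer RNG seed; all simulation is deterministic given the
#'   configuration.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 5000,
                       n_reps = 3,
                       class_counts = c(tmg3_up = 150, tmg3_down = 150,
                                        tmg2_only_up = 100, tmg2_only_down = 100,
                                        transient = 200, fluctuating = 100),
                       base_lfc = 2,
                       attenuation = c(P2 = 0.7, P3 = 0.5, P4 = 1.2),
                       dispersion_range = c(0.01, 0.5),
                       libsize_range = c(0.7, 1.4),
                       baseline_range = c(20, 2000),
                       n_traits_weaken = 3,
                       n_traits_strengthen = 3,
                       n_traits_null = 2,
                       trait_reps = 6,
                       trait_baseline = 100,
                       trait_effect = 30,
                       trait_noise_frac = 0.05,
                       seed = 1L) {
  cls_names <- c("tmg3_up", "tmg3_down", "tmg2_only_up", "tmg2_only_down",
                 "transient", "fluctuating")
  if (is.null(class_counts) || length(class_counts) == 0) {
    class_counts <- stats::setNames(integer(length(cls_names)), cls_names)
  }
  if (is.null(names(class_counts)) || !all(names(class_counts) %in% cls_names)) {
    stop("class_counts must be named with a subset of: ",
         paste(cls_names, collapse = ", "))
  }
  full <- stats::setNames(integer(length(cls_names)), cls_names)
  full[names(class_counts)] <- as.integer(class_counts)
  if (any(full < 0)) stop("class_counts must be non-negative")
  if (sum(full) > n_genes) stop("sum of class_counts exceeds n_genes")
  if (n_genes < 1 || n_reps < 1) stop("n_genes and n_reps must be positive")
  if (length(dispersion_range) != 2 || any(dispersion_range <= 0) ||
      dispersion_range[1] > dispersion_range[2]) {
    stop("dispersion_range must be a positive increasing interval")
  }
  if (length(libsize_range) != 2 || any(libsize_range <= 0) ||
      libsize_range[1] > libsize_range[2]) {
    stop("libsize_range must be a positive increasing interval")
  }
  if (any(baseline_range <= 0)) stop("baseline_range must be positive")
  if (!all(c("P2", "P3", "P4") %in% names(attenuation))) {
    stop("attenuation needs named multipliers P2, P3, P4")
  }
  if (trait_reps < 2) stop("trait_reps must be at least 2")
  if (trait_effect <= 0 || trait_noise_frac < 0) {
    stop("trait_effect must be positive and trait_noise_frac non-negative")
  }
  cfg <- list(n_genes = as.integer(n_genes), n_reps = as.integer(n_reps),
              class_counts = full, base_lfc = base_lfc,
              attenuation = attenuation[c("P2", "P3", "P4")],
              dispersion_range = dispersion_range,
              libsize_range = libsize_range,
              baseline_range = baseline_range,
              n_traits_weaken = as.integer(n_traits_weaken),
              n_traits_strengthen = as.integer(n_traits_strengthen),
              n_traits_null = as.integer(n_traits_null),
              trait_reps = as.integer(trait_reps),
              trait_baseline = trait_baseline,
              trait_effect = trait_effect,
              trait_noise_frac = trait_noise_frac,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes x 5 groups x", x$n_reps, "reps\n")
  cat("  planted:", paste(names(x$class_counts), x$class_counts,
                          sep = "=", collapse = ", "), "\n")
  cat("  base_lfc:", x$base_lfc, " attenuation:",
      paste(names(x$attenuation), x$attenuation, sep = "=", collapse = ", "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Sequenced group design of the four-stage experiment
#'
#' The five sequenced groups and their design labels: stage (P1-P4),
#' lineage (descendants of the control or of the stressed P1 founders) and
#' cultivation condition at sampling time.
#'
#' @return data.frame with columns group, stage, lineage, condition.
#' @export
design_groups <- function() {
  data.frame(
    group = c("CK", "S", "P1S-P2CK", "P1S-P3CK", "P1S-P4S"),
    stage = c("P1", "P1", "P2", "P3", "P4"),
    lineage = c("P1CK", "P1S", "P1S", "P1S", "P1S"),
    condition = c("CK", "S", "CK", "CK", "S"),
    stringsAsFactors = FALSE
  )
}

# per-gene log2 effect in each contrast group (columns S, P2, P3, P4)
sim_lfc_schedule <- function(cfg) {
  att <- cfg$attenuation
  n <- cfg$n_genes
  cc <- cfg$class_counts
  lfc <- matrix(0, nrow = n, ncol = 4,
                dimnames = list(NULL, c("S", "P2", "P3", "P4")))
  cls <- rep("null", n)
  base <- cfg$base_lfc
  i <- 0L
  take <- function(k) {
    idx <- seq_len(k) + i
    i <<- i + k
    idx
  }
  prof <- c(1, att[["P2"]], att[["P3"]], att[["P4"]])
  for (nm in names(cc)) {
    k <- cc[[nm]]
    if (k == 0) next
    idx <- take(k)
    cls[idx] <- nm
    sgn <- switch(nm,
      tmg3_up = , tmg2_only_up = rep(1, k),
      tmg3_down = , tmg2_only_down = rep(-1, k),
      transient = rep(c(1, -1), length.out = k),
      fluctuating = rep(1, k))
    eff <- switch(nm,
      tmg3_up = , tmg3_down = outer(rep(base, k), prof),
      tmg2_only_up = , tmg2_only_down =
        outer(rep(base, k), c(1, att[["P2"]], 0, att[["P4"]])),
      transient = outer(rep(base, k), c(1, 0, 0, 0)),
      fluctuating = outer(rep(base, k), prof * c(1, -1, 1, -1)))
    lfc[idx, ] <- eff * sgn
  }
  sign <- ifelse(cls == "null", "none",
          ifelse(cls == "fluctuating", "mixed",
          ifelse(lfc[, "S"] > 0, "up", "down")))
  list(lfc = lfc, class = cls, sign = sign)
}
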