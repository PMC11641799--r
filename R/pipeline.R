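#' Run the full transcriptional-memory pipeline
#'
#' Executes every stage on either simulated or user-supplied data:
#' \enumerate{
#'   \item simulate (or load) counts and traits;
#'   \item differential expression of the four generation contrasts vs CK;
#'   \item memory classification (robust / TMG2 / TMG3 / pattern taxonomy);
#'   \item trait reaction-norm classification (weaken / strengthen);
#'   \item co-expression network on the DEG union (standardized log2
#'     normalized counts), module-trait association with the classified
#'     traits, hub genes, and TMG share per module class;
#'   \item a machine-readable run report.
#' }
#' Deterministic given the configuration seed. When `outdir` is given, all
#' stage outputs (TSV/CSV tables, the JSON report and the resolved
#' configuration) are written there.
#'
#' @param cfg a [sim_config()] (simulation mode), or a list with elements
#'   `counts`, `samples`, `traits` (and optionally `trait_classes`) for real
#'   data.
#' @param alpha adjusted-p threshold for DE and LSD calls (default 0.05).
#' @param lfc_threshold absolute log2-fold-change threshold (default 0.5).
#' @param power soft-thresholding power (default 20).
#' @param min_module_size,merge_cut,edge_top,hub_top network parameters,
#'   see [build_network()].
#' @param outdir optional output directory.
#' @param quiet suppress progress messages.
#' @return list of class `run_report` — see [validate_report()] for the
#'   schema; also carries the full stage objects in attribute `stages`.
#' @export
run_pipeline <- function(cfg = sim_config(), alpha = 0.05, lfc_threshold = 0.5,
                         power = 20, min_module_size = 30, merge_cut = 0.25,
                         edge_top = 0.30, hub_top = 0.10, outdir = NULL,
                         quiet = TRUE) {
  say <- function(...) if (!quiet) message(...)
  truth <- NULL
  if (inherits(cfg, "sim_config")) {
    say("simulating counts and traits (seed ", cfg$seed, ")")
    sim <- simulate_counts(cfg)
    tra <- simulate_traits(cfg)
    counts <- sim$counts
    samples <- sim$samples
    trait_table <- tra$traits
    truth <- list(genes = sim$truth, traits = tra$truth)
    seed <- cfg$seed
  } else {
    counts <- cfg$counts
    samples <- cfg$samples
    trait_table <- cfg$traits
    seed <- if (!is.null(cfg$seed)) cfg$seed else NA_integer_
  }

  say("differential expression (4 contrasts vs CK)")
  contrasts <- run_contrasts(counts, samples, alpha = alpha,
                             lfc_threshold = lfc_threshold, quiet = quiet)
  deg_counts <- lapply(contrasts, function(x) {
    list(up = sum(x$direction == "up"), down = sum(x$direction == "down"))
  })

  say("memory classification")
  dirs <- direction_table(contrasts, quiet = quiet)
  mem <- classify_patterns(dirs)
  mem_sum <- summary(mem)

  say("trait classification")
  trait_cls <- classify_traits(trait_table, alpha = alpha)
  trait_classes <- stats::setNames(trait_cls$label, trait_cls$trait)

  say("co-expression network on the DEG union")
  deg_union <- unique(unlist(lapply(contrasts, function(x) {
    x$gene_id[x$direction != "ns"]
  })))
  net <- NULL; assoc <- NULL; enr <- NULL
  module_count <- 0L
  if (length(deg_union) >= max(2 * min_module_size, 10)) {
    sf <- size_factors(counts)
    y <- sweep(counts[deg_union, , drop = FALSE], 2, sf, "/")
    expr <- standardize_expression(y)
    net <- build_network(expr, power = power,
                         min_module_size = min_module_size,
                         merge_cut = merge_cut, edge_top = edge_top,
                         hub_top = hub_top)
    module_count <- length(setdiff(unique(net$modules), "grey"))
    if (module_count >= 1 && ncol(net$eigengenes) >= 1) {
      st <- sample_trait_matrix(trait_table, samples)
      assoc <- module_trait_association(net$eigengenes, st,
                                        trait_classes = trait_classes)
      mod_class <- stats::setNames(assoc$module_class,
                                   sub("^ME", "", names(assoc$module_class)))
      enr <- tmg_module_enrichment(net$modules, mod_class, mem,
                                   hubs = net$hubs)
    }
  } else {
    say("DEG union too small for network construction; skipping")
  }

  report <- list(
    seed = seed,
    config = list(alpha = alpha, lfc_threshold = lfc_threshold, power = power,
                  min_module_size = min_module_size, merge_cut = merge_cut,
                  edge_top = edge_top, hub_top = hub_top,
                  n_genes = nrow(counts), n_samples = ncol(counts)),
    n_genes_tested = nrow(dirs),
    deg_counts = deg_counts,
    pattern_counts = mem_sum$label_counts,
    tmg2 = list(up = mem_sum$tmg2_up, down = mem_sum$tmg2_down,
                total = mem_sum$tmg2_up + mem_sum$tmg2_down),
    tmg3 = list(up = mem_sum$tmg3_up, down = mem_sum$tmg3_down,
                total = mem_sum$tmg3_up + mem_sum$tmg3_down),
    trait_classes = as.list(trait_classes),
    module_count = module_count,
    module_sizes = if (!is.null(net)) {
      as.list(table(net$modules[net$modules != "grey"]))
    } else list(),
    module_classes = if (!is.null(assoc) && !is.null(assoc$module_class)) {
      as.list(assoc$module_class)
    } else list(),
    tmg_fraction_by_class = if (!is.null(enr)) {
      stats::setNames(as.list(enr$fractions$fraction), enr$fractions$class)
    } else list(),
    tmg_enrichment_p = if (!is.null(enr)) enr$fisher_p else NA_real_,
    hub_counts = if (!is.null(net)) {
      as.list(vapply(net$hubs, length, integer(1)))
    } else list(),
    hub_tmg_percent = if (!is.null(enr)) enr$hub_tmg_percent else NA_real_,
    versions = list(r = as.character(getRversion()),
                    clonemem = as.character(utils::packageVersion("clonemem")))
  )
  class(report) <- c("run_report", "list")
  validate_report(report)
  attr(report, "stages") <- list(counts = counts, samples = samples,
                                 traits = trait_table, contrasts = contrasts,
                                 directions = dirs, memory = mem,
                                 trait_classification = trait_cls,
                                 network = net, association = assoc,
                                 enrichment = enr, truth = truth)
  if (!is.null(outdir)) write_pipeline_outputs(report, outdir)
  report
}

#' Validate a run report against the bundled schema
#'
#' Structural check of required fields, types and internal consistency
#' (TMG3 nested in TMG2, per-contrast up+down consistency, pattern counts
#' summing to the gene universe). The machine-readable schema ships at
#' `system.file("extdata", "report-schema.json", package = "clonemem")`.
#'
#' @param report a `run_report` list.
#' @return TRUE invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(system.file("extdata", "report-schema.json",
                                            package = "clonemem"))
  for (field in names(schema$required)) {
    if (is.null(report[[field]])) stop("report missing field: ", field)
    type <- schema$required[[field]]
    ok <- switch(type,
                 number = is.numeric(report[[field]]) || is.na(report[[field]]),
                 object = is.list(report[[field]]),
                 TRUE)
    if (!ok) stop("report field '", field, "' should be of type ", type)
  }
  if (report$tmg3$total > report$tmg2$total) {
    stop("inconsistent report: TMG3 count exceeds TMG2 count")
  }
  pat <- sum(unlist(report$pattern_counts))
  if (pat != report$n_genes_tested) {
    stop("inconsistent report: pattern counts do not sum to the gene universe")
  }
  invisible(TRUE)
}

write_pipeline_outputs <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  st <- attr(report, "stages")
  write_counts(st$counts, file.path(outdir, "counts.tsv"))
  utils::write.csv(st$samples, file.path(outdir, "samples.csv"),
                   row.names = FALSE)
  utils::write.csv(st$traits, file.path(outdir, "traits.csv"),
                   row.names = FALSE)
  for (nm in names(st$contrasts)) {
    write_contrast(st$contrasts[[nm]],
                   file.path(outdir, paste0("de_", nm, ".tsv")))
  }
  utils::write.csv(as.data.frame(st$memory),
                   file.path(outdir, "memory_classification.csv"),
                   row.names = FALSE)
  utils::write.csv(st$trait_classification,
                   file.path(outdir, "trait_classification.csv"),
                   row.names = FALSE)
  if (!is.null(st$network)) {
    utils::write.csv(data.frame(gene_id = names(st$network$modules),
                                module = st$network$modules,
                                degree = st$network$degree[names(st$network$modules)],
                                row.names = NULL),
                     file.path(outdir, "modules.csv"), row.names = FALSE)
    utils::write.table(st$network$edges, file.path(outdir, "edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.csv(data.frame(sample_id = rownames(st$network$eigengenes),
                                st$network$eigengenes, row.names = NULL,
                                check.names = FALSE),
                     file.path(outdir, "eigengenes.csv"), row.names = FALSE)
    hubs <- st$network$hubs
    utils::write.csv(data.frame(module = rep(names(hubs), lengths(hubs)),
                                gene_id = unlist(hubs), row.names = NULL),
                     file.path(outdir, "hub_genes.csv"), row.names = FALSE)
  }
  if (!is.null(st$truth)) {
    utils::write.csv(st$truth$genes, file.path(outdir, "truth_genes.csv"),
                     row.names = FALSE)
    utils::write.csv(st$truth$traits, file.path(outdir, "truth_traits.csv"),
                     row.names = FALSE)
  }
  rep_plain <- unclass(report)
  attr(rep_plain, "stages") <- NULL
  jsonlite::write_json(rep_plain, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(outdir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run report (seed ", x$seed, ", ", x$n_genes_tested,
      " genes tested)\n", sep = "")
  for (nm in names(x$deg_counts)) {
    cat(sprintf("  %s: %d up / %d down\n", nm, x$deg_counts[[nm]]$up,
                x$deg_counts[[nm]]$down))
  }
  cat(sprintf("  TMG2: %d (%d up / %d down); TMG3: %d (%d up / %d down)\n",
              x$tmg2$total, x$tmg2$up, x$tmg2$down,
              x$tmg3$total, x$tmg3$up, x$tmg3$down))
  cat("  traits:", paste(names(x$trait_classes), unlist(x$trait_classes),
                         sep = "=", collapse = ", "), "\n")
  cat("  modules:", x$module_count, "\n")
  invisible(x)
}
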