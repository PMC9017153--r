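# End-to-end pipelines: QC -> enrichment/discovery -> assignment -> MLE,
# driven by a single configuration list (or YAML file). Each stage logs
# its timing to stderr, failures abort with a stage label, and every
# written artifact embeds the configuration hash for provenance.

.pipeline_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  message(sprintf("[%s] start", name))
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
  message(sprintf("[%s] done (%.1f s)", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

# Materialize one configured sample: either a prebuilt SequencingSample
# (`sample`), raw insert strings (`reads`), or a FASTQ file (`file`,
# QC-filtered and trimmed).
.load_sample <- function(entry, cfg) {
  id <- entry$id %||% entry$file %||% "sample"
  role <- entry$role
  condition <- as.character(entry$df %||% entry$time %||% "")
  if (!is.null(entry$sample)) {
    stopifnot(inherits(entry$sample, "SequencingSample"))
    return(entry$sample)
  }
  if (!is.null(entry$reads)) {
    return(sequencing_sample(id, as_dna(entry$reads), role = role,
                             condition = condition))
  }
  records <- read_fastq_records(entry$file)
  qc_filter_and_trim(records,
                     insert_length = cfg$insert_length %||% 20L,
                     min_quality = cfg$min_quality %||% 20L,
                     sample_id = id, role = role, condition = condition)
}

.validate_pipeline_config <- function(cfg, type) {
  stopifnot(is.list(cfg), !is.null(cfg$samples), length(cfg$samples) >= 2)
  for (s in cfg$samples) {
    if (is.null(s$role)) stop("every sample needs a 'role'")
    if (is.null(s$sample) && is.null(s$reads) && is.null(s$file)) {
      stop("every sample needs one of 'sample', 'reads' or 'file'")
    }
    if (!is.null(s$file) && !file.exists(s$file)) {
      stop("sample file not found: ", s$file)
    }
  }
  roles <- vapply(cfg$samples, `[[`, character(1), "role")
  if (sum(roles == "pool") != 1) {
    stop("configuration must contain exactly one pool sample")
  }
  if (type == "equilibrium") {
    bound <- cfg$samples[roles == "bound"]
    if (!length(bound)) stop("no bound samples configured")
    dfs <- vapply(bound, function(s) as.numeric(s$df %||% NA_real_),
                  numeric(1))
    if (anyNA(dfs)) stop("every bound sample needs a dilution factor 'df'")
    if (sum(dfs == 0) != 1) {
      stop("equilibrium runs need exactly one no-protein control (df = 0)")
    }
  } else {
    tps <- cfg$samples[roles == "timepoint"]
    times <- vapply(tps, function(s) as.numeric(s$time %||% NA_real_),
                    numeric(1))
    if (length(tps) < 4 || anyNA(times)) {
      stop("kinetics runs need >= 4 timepoint samples with 'time' fields")
    }
    if (is.null(cfg$kinetics$protein_nM)) {
      stop("kinetics runs need kinetics$protein_nM")
    }
  }
  if (is.null(cfg$mirna$guide) && is.null(cfg$sites)) {
    stop("configuration needs either 'mirna' (for discovery) or 'sites'")
  }
  invisible(TRUE)
}

.site_motifs_from_config <- function(cfg, bound, pool, control) {
  if (!is.null(cfg$sites)) {
    motifs <- unlist(cfg$sites)
    return(list(motifs = setNames(as.character(motifs), names(motifs)),
                discovery = NULL))
  }
  guide <- mirna(cfg$mirna$name %||% "guide", cfg$mirna$guide)
  disc <- discover_sites(bound, pool, control = control, mirna = guide,
                         k = cfg$k %||% 10L,
                         region = cfg$region %||% "full",
                         n_top = cfg$discovery$n_top %||% 100L)
  if (!nrow(disc$sites)) {
    stop("discovery found no significant sites (stop reason: ",
         disc$stop_reason, ")")
  }
  list(motifs = setNames(disc$sites$motif, disc$sites$label),
       discovery = disc)
}

.assign_region <- function(cfg) {
  reg <- cfg$region %||% "full"
  if (identical(reg, "full")) NULL else as.numeric(reg)
}

.write_artifacts <- function(out, dir, cfg_hash) {
  if (is.null(dir)) return(invisible(NULL))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeLines(cfg_hash, file.path(dir, "config_hash.txt"))
  write_count_matrix(out$counts, file.path(dir, "site_counts.tsv"))
  write_estimates_tsv(out$estimates, file.path(dir, "estimates.tsv"))
  if (!is.null(out$discovery)) {
    write_discovery_tsv(out$discovery, file.path(dir, "discovery.tsv"))
  }
  invisible(NULL)
}

#' Run the equilibrium analysis pipeline
#'
#' Stages: sample loading/QC, site discovery (skipped when the
#' configuration lists site motifs explicitly), read assignment, and
#' maximum-likelihood K_D estimation. Deterministic given
#' \code{config$seed}.
#'
#' @param config configuration list or path to a YAML/JSON file. Required
#'   fields: \code{samples} (each with \code{role} of \code{"pool"} or
#'   \code{"bound"}, a \code{df} dilution factor for bound samples — the
#'   no-protein control is the bound sample with \code{df = 0} — and one
#'   of \code{file}/\code{reads}/\code{sample}), plus either
#'   \code{mirna} (\code{name}, \code{guide}) for de novo discovery or
#'   \code{sites} (label -> motif). Optional: \code{k}, \code{region},
#'   \code{assignment_mode}, \code{total_rna_nM} (default 100),
#'   \code{protocol} (\code{n_boot}, \code{n_starts}, \code{boot_frac},
#'   \code{retain_r}), \code{seed}, \code{output_dir}.
#' @return list with \code{discovery} (or NULL), \code{counts}
#'   (\code{SiteCountMatrix}), \code{design}, \code{estimates}
#'   (\code{EstimateSummary}) and \code{config_hash}.
#' @export
run_equilibrium_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  .validate_pipeline_config(config, "equilibrium")
  cfg_hash <- config_hash(config)
  message("pipeline config hash: ", cfg_hash)
  samples <- .pipeline_stage("qc", lapply(config$samples, .load_sample,
                                          cfg = config))
  roles <- vapply(config$samples, `[[`, character(1), "role")
  dfs <- vapply(config$samples, function(s)
    as.numeric(s$df %||% NA_real_), numeric(1))
  pool <- samples[[which(roles == "pool")]]
  bound_idx <- which(roles == "bound")
  ctrl_idx <- bound_idx[dfs[bound_idx] == 0]
  top_idx <- bound_idx[which.max(dfs[bound_idx])]
  sites <- .pipeline_stage("discovery", .site_motifs_from_config(
    config, samples[[top_idx]], pool, samples[[ctrl_idx]]))
  mode <- config$assignment_mode %||% "exclusive"
  region <- .assign_region(config)
  asn <- .pipeline_stage("assignment", {
    a <- lapply(samples[c(which(roles == "pool"), bound_idx)],
                assign_reads, motifs = sites$motifs, region = region,
                mode = mode)
    names(a) <- c("pool", paste0("df", dfs[bound_idx]))
    a
  })
  counts <- site_count_matrix(asn[-1])
  poolcomp <- pool_site_concentrations(asn[[1]],
                                       config$total_rna_nM %||% 100)
  design <- eq_design(poolcomp, setNames(dfs[bound_idx], colnames(counts)))
  p <- config$protocol %||% list()
  estimates <- .pipeline_stage("mle", estimate_kd(
    counts, design,
    n_boot = p$n_boot %||% 10L, n_starts = p$n_starts %||% 100L,
    boot_frac = p$boot_frac %||% 0.95, retain_r = p$retain_r %||% 0.90,
    seed = config$seed))
  out <- list(discovery = sites$discovery, counts = counts,
              design = design, estimates = estimates,
              config_hash = cfg_hash)
  .write_artifacts(out, config$output_dir, cfg_hash)
  out
}

#' Run the kinetics analysis pipeline
#'
#' Stages: sample loading/QC, read assignment against configured (or
#' discovered) site motifs, and maximum-likelihood rate-constant
#' estimation. Deterministic given \code{config$seed}.
#'
#' @param config as in \code{\link{run_equilibrium_pipeline}}, but
#'   samples with \code{role = "timepoint"} carry a \code{time} (s;
#'   >= 4 required) and \code{config$kinetics$protein_nM} gives the total
#'   protein concentration. Discovery, when needed, runs on the latest
#'   time point.
#' @return list with \code{discovery} (or NULL), \code{counts},
#'   \code{design}, \code{estimates} and \code{config_hash}.
#' @export
run_kinetics_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  .validate_pipeline_config(config, "kinetics")
  cfg_hash <- config_hash(config)
  message("pipeline config hash: ", cfg_hash)
  samples <- .pipeline_stage("qc", lapply(config$samples, .load_sample,
                                          cfg = config))
  roles <- vapply(config$samples, `[[`, character(1), "role")
  times <- vapply(config$samples, function(s)
    as.numeric(s$time %||% NA_real_), numeric(1))
  pool <- samples[[which(roles == "pool")]]
  tp_idx <- which(roles == "timepoint")
  tp_idx <- tp_idx[order(times[tp_idx])]
  sites <- .pipeline_stage("discovery", .site_motifs_from_config(
    config, samples[[tp_idx[length(tp_idx)]]], pool, control = NULL))
  mode <- config$assignment_mode %||% "exclusive"
  region <- .assign_region(config)
  asn <- .pipeline_stage("assignment", {
    a <- lapply(samples[c(which(roles == "pool"), tp_idx)],
                assign_reads, motifs = sites$motifs, region = region,
                mode = mode)
    names(a) <- c("pool", paste0("t", times[tp_idx]))
    a
  })
  counts <- site_count_matrix(asn[-1])
  poolcomp <- pool_site_concentrations(asn[[1]],
                                       config$total_rna_nM %||% 100)
  design <- kin_design(poolcomp, protein = config$kinetics$protein_nM,
                       times = times[tp_idx])
  p <- config$protocol %||% list()
  estimates <- .pipeline_stage("mle", estimate_kinetics(
    counts, design,
    n_boot = p$n_boot %||% 10L, n_starts = p$n_starts %||% 100L,
    boot_frac = p$boot_frac %||% 0.95, retain_r = p$retain_r %||% 0.90,
    seed = config$seed))
  out <- list(discovery = sites$discovery, counts = counts,
              design = design, estimates = estimates,
              config_hash = cfg_hash)
  .write_artifacts(out, config$output_dir, cfg_hash)
  out
}
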