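# Read-level pipeline fixtures: planted-motif synthetic samples whose
# planted fractions follow the binding model, so the estimation stage has
# a coherent signal to fit.

wb_motifs <- c("8mer" = "CUACCUCA", "7mer-m8" = "CUACCUC",
               "7mer-A1" = "UACCUCA")

wb_eq_config <- function(n = 20000, seed = 1000) {
  pool_conc <- c("8mer" = 0.5, "7mer-m8" = 0.5, "7mer-A1" = 0.5,
                 "no-site" = 98.5)
  truth <- eq_params(c("8mer" = 0.02, "7mer-m8" = 0.1, "7mer-A1" = 0.5,
                       "no-site" = 5), ago = 2.1, background = 0.1)
  dfs <- c(0.4, 0.1, 0)
  samples <- list(list(
    id = "pool", role = "pool",
    sample = generate_synthetic_reads(
      n, planted = setNames(as.numeric(pool_conc[1:3] / 100),
                            wb_motifs),
      sample_id = "pool", seed = seed)))
  for (i in seq_along(dfs)) {
    p <- attr(predict_composition(truth, pool_conc, dfs[i]), "p")
    samples[[i + 1]] <- list(
      id = paste0("b", i), role = "bound", df = dfs[i],
      sample = generate_synthetic_reads(
        n, planted = setNames(as.numeric(p[1:3]), wb_motifs),
        sample_id = paste0("b", i), role = "bound", seed = seed + i))
  }
  list(samples = samples, sites = as.list(wb_motifs),
       protocol = list(n_boot = 2, n_starts = 4), seed = 17)
}

test_that("invalid pipeline configurations fail before any compute", {
  base <- list(samples = list(
    list(id = "p", role = "pool", reads = "ACGTACGTACGTACGTACGT"),
    list(id = "b", role = "bound", df = 0.4,
         reads = "ACGTACGTACGTACGTACGT")),
    sites = list("8mer" = "CUACCUCA"))
  # no no-protein control
  expect_error(run_equilibrium_pipeline(base), "no-protein")
  # no pool
  cfg <- base
  cfg$samples[[1]]$role <- "bound"; cfg$samples[[1]]$df <- 0
  expect_error(run_equilibrium_pipeline(cfg), "exactly one pool")
  # bound sample without a dilution factor
  cfg <- base
  cfg$samples[[2]]$df <- NULL
  expect_error(run_equilibrium_pipeline(cfg), "dilution factor")
  # neither discovery guide nor explicit sites
  cfg <- base
  cfg$samples[[2]]$df <- 0
  cfg$sites <- NULL
  expect_error(run_equilibrium_pipeline(cfg), "'mirna'|'sites'")
  # kinetics: too few time points
  kcfg <- list(samples = list(
    list(id = "p", role = "pool", reads = "ACGTACGTACGTACGTACGT"),
    list(id = "t1", role = "timepoint", time = 0,
         reads = "ACGTACGTACGTACGTACGT")),
    sites = list("8mer" = "CUACCUCA"),
    kinetics = list(protein_nM = 0.15))
  expect_error(run_kinetics_pipeline(kcfg), ">= 4 timepoint")
  # missing sample source
  cfg <- base
  cfg$samples[[2]] <- list(id = "b", role = "bound", df = 0)
  expect_error(run_equilibrium_pipeline(cfg), "one of")
})

test_that("the equilibrium pipeline runs end to end and is deterministic", {
  cfg <- wb_eq_config()
  out_dir <- file.path(tempfile(), "run1")
  cfg$output_dir <- out_dir
  out1 <- suppressMessages(run_equilibrium_pipeline(cfg))
  expect_null(out1$discovery)   # explicit sites skip discovery
  expect_s3_class(out1$counts, "SiteCountMatrix")
  expect_equal(rownames(out1$counts), c(names(wb_motifs), "no-site"))
  expect_s3_class(out1$estimates, "EstimateSummary")
  expect_match(out1$config_hash, "^[0-9a-f]{8}$")
  # artifacts embed the configuration hash
  expect_equal(readLines(file.path(out_dir, "config_hash.txt")),
               out1$config_hash)
  expect_true(file.exists(file.path(out_dir, "site_counts.tsv")))
  expect_true(file.exists(file.path(out_dir, "estimates.tsv")))
  # rerun with the same seed: byte-identical estimate tables
  cfg2 <- wb_eq_config()
  cfg2$output_dir <- file.path(tempfile(), "run2")
  out2 <- suppressMessages(run_equilibrium_pipeline(cfg2))
  expect_identical(as.data.frame(out1$estimates),
                   as.data.frame(out2$estimates))
  expect_identical(readLines(file.path(out_dir, "estimates.tsv")),
                   readLines(file.path(cfg2$output_dir, "estimates.tsv")))
})

test_that("the discovery stage slots into the equilibrium pipeline", {
  # deep enough that pool-count noise cannot scramble the k-mer ranking:
  # at this depth the full-length planted sites strictly out-enrich their
  # flanking-context k-mers, so discovery reports them first
  cfg <- wb_eq_config(n = 100000, seed = 2000)
  cfg$sites <- NULL
  cfg$mirna <- list(name = "let-7a", guide = "UGAGGUAGUAGGUUGUAUAGUU")
  cfg$k <- 8
  out <- suppressMessages(run_equilibrium_pipeline(cfg))
  expect_s3_class(out$discovery, "DiscoveryResult")
  expect_true("8mer" %in% out$discovery$sites$label)
  expect_true(all(out$discovery$sites$label %in% rownames(out$counts)))
})

test_that("the kinetics pipeline runs end to end and is deterministic", {
  pool_conc <- c("8mer" = 0.5, "7mer-m8" = 0.5, "7mer-A1" = 0.5,
                 "no-site" = 98.5)
  truth <- kin_params(
    c("8mer" = 0.05, "7mer-m8" = 0.01, "7mer-A1" = 0.002,
      "no-site" = 0.001),
    c("8mer" = 1e-3, "7mer-m8" = 5e-3, "7mer-A1" = 0.01, "no-site" = 10),
    background = 0.1)
  times <- c(0, 60, 300, 1800, 7200)
  build <- function() {
    samples <- list(list(
      id = "pool", role = "pool",
      sample = generate_synthetic_reads(
        15000, planted = setNames(as.numeric(pool_conc[1:3] / 100),
                                  wb_motifs),
        sample_id = "pool", seed = 3000)))
    for (i in seq_along(times)) {
      p <- attr(predict_composition_t(truth, pool_conc, 2, times[i]), "p")
      samples[[i + 1]] <- list(
        id = paste0("t", times[i]), role = "timepoint", time = times[i],
        sample = generate_synthetic_reads(
          15000, planted = setNames(as.numeric(p[1:3]), wb_motifs),
          sample_id = paste0("t", times[i]), role = "timepoint",
          seed = 3000 + i))
    }
    list(samples = samples, sites = as.list(wb_motifs),
         kinetics = list(protein_nM = 2),
         protocol = list(n_boot = 1, n_starts = 3), seed = 19)
  }
  # some jittered optimizer starts stray into the zero-prediction penalty
  # region by design; those warnings are expected here
  out1 <- suppressWarnings(suppressMessages(run_kinetics_pipeline(build())))
  expect_s3_class(out1$estimates, "EstimateSummary")
  expect_equal(colnames(out1$counts), paste0("t", times))
  out2 <- suppressWarnings(suppressMessages(run_kinetics_pipeline(build())))
  expect_identical(as.data.frame(out1$estimates),
                   as.data.frame(out2$estimates))
})

test_that("the command-line entry point ships and parses", {
  cli <- system.file("cli", "rbns.R", package = "rbnskit")
  expect_true(nzchar(cli))
  expect_error(parse(cli), NA)
})
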