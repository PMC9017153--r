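# Plain-text artifact input/output: count matrices (TSV + JSON sidecar),
# estimate tables and pipeline configuration files. Every artifact is
# re-loadable so pipelines can resume from any stage.

#' Write a site-by-sample count matrix as TSV with a JSON sidecar
#'
#' The sidecar (\code{<path>.json}) stores the assignment mode and
#' per-sample excluded-read counts so the matrix round-trips through
#' \code{\link{read_count_matrix}}.
#'
#' @param counts matrix from \code{\link{site_count_matrix}} (or any
#'   named sites x samples matrix).
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(site = rownames(counts),
                   as.data.frame(unclass(counts), check.names = FALSE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(mode = attr(counts, "mode_assign"),
               excluded = as.list(attr(counts, "excluded")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_count_matrix
#' @return for the reader: the count matrix with attributes restored.
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$site
  sidecar <- paste0(path, ".json")
  mode_assign <- NULL; excluded <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    mode_assign <- meta$mode
    excluded <- unlist(meta$excluded)
  }
  structure(m, class = c("SiteCountMatrix", "matrix"),
            mode_assign = mode_assign, excluded = excluded)
}

#' Write an estimate summary as TSV
#'
#' @param summary an \code{EstimateSummary} from \code{\link{estimate_kd}}
#'   or \code{\link{estimate_kinetics}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_estimates_tsv <- function(summary, path) {
  write.table(as.data.frame(summary), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' @param path YAML (or JSON) configuration file.
#' @return the configuration list with attribute \code{config_hash}.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  attr(cfg, "config_hash") <- config_hash(cfg)
  cfg
}

#' Stable short hash of a configuration (32-bit FNV-1a over its
#' serialization)
#'
#' Embedded in every pipeline artifact for provenance.
#'
#' @param config a configuration list.
#' @return 8-character hexadecimal string.
#' @export
config_hash <- function(config) {
  attr(config, "config_hash") <- NULL
  bytes <- as.integer(serialize(config, NULL, version = 2L)[-(1:14)])
  # skip the serialization header (bytes 1-14) so the hash depends only
  # on content, not on the writing R version string
  h <- 2166136261
  # multiply mod 2^32 in 16-bit halves to stay within double precision
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- (h %% 65536 * 16777619 +
            (h %/% 65536 * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
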