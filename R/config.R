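#' Default run configuration
#'
#' Every threshold the pipeline uses lives in the configuration so that runs
#' are reproducible from a single file. Defaults follow the thresholds used
#' throughout: mean mappability below 0.85 filters an enhancer out, candidate
#' peaks must be at least 3 kb from any TSS or H3K4me3-enriched region, genes
#' are assigned to enhancers up to 100 kb away, H3K27ac status uses a 2 kb
#' distance, and model selection keeps the top 5\% of subset models under
#' 10-fold nested cross-validation.
#'
#' @param ... named overrides of any default field.
#' @return A named list of class \code{erna_config}.
#' @export
default_config <- function(...) {
  cfg <- list(
    tracks = list(),            # mark name -> read BED path
    gro_track = NULL,           # stranded GRO-seq read BED path
    p300_peaks = NULL,
    h3k4me1_peaks = NULL,
    h3k4me3_peaks = NULL,
    h3k27ac_peaks = NULL,
    gene_table = NULL,
    mappability = NULL,
    expression = NULL,
    provenance = "P300",
    mappability_min = 0.85,
    tss_exclusion_bp = 3000,
    gene_assign_max_bp = 100000,
    k27ac_dist_bp = 2000,
    window_half_bp = 1000,
    pseudocount = 1,
    log_base = 2,
    folds = 10,
    inner_folds = 10,
    top_n_inner = 10,
    top_fraction = 0.05,
    relative_ratio = 0.95,
    max_subset_size = 4,
    ridge = 1e-6,
    seed = 1
  )
  over <- list(...)
  cfg[names(over)] <- over
  validate_config(cfg)
}

validate_config <- function(cfg) {
  num_pos <- c("mappability_min", "tss_exclusion_bp", "gene_assign_max_bp",
               "k27ac_dist_bp", "window_half_bp", "log_base")
  for (f in num_pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0) {
      stop("config: '", f, "' must be a positive number", call. = FALSE)
    }
  }
  if (cfg$pseudocount < 0) stop("config: pseudocount must be >= 0", call. = FALSE)
  if (cfg$folds < 2) stop("config: folds must be >= 2", call. = FALSE)
  if (cfg$inner_folds < 2) stop("config: inner_folds must be >= 2", call. = FALSE)
  if (cfg$top_fraction <= 0 || cfg$top_fraction > 1) {
    stop("config: top_fraction must be in (0, 1]", call. = FALSE)
  }
  structure(cfg, class = "erna_config")
}

#' Load a run configuration from a YAML file
#'
#' Absent keys take the documented defaults of [default_config()]. Track
#' paths are under a \code{tracks:} mapping of mark name to read BED path.
#'
#' @param path path to a YAML configuration file.
#' @return A validated \code{erna_config} list.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config: expected a YAML mapping", call. = FALSE)
  known <- names(default_config())
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("config: unknown key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(default_config, raw)
}

#' @export
print.erna_config <- function(x, ...) {
  cat("eRNA pipeline configuration\n")
  cat("  tracks:", length(x$tracks), "mark track(s)\n")
  for (f in c("mappability_min", "tss_exclusion_bp", "gene_assign_max_bp",
              "k27ac_dist_bp", "window_half_bp", "pseudocount", "log_base",
              "folds", "inner_folds", "top_n_inner", "top_fraction", "seed")) {
    cat(sprintf("  %-18s %s\n", f, format(x[[f]])))
  }
  invisible(x)
}
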