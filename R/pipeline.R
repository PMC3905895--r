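## ---- model serialization (full precision, text) ----

#' Serialize / restore a fitted model as text
#'
#' Tab-separated key/field/value rows with full floating-point precision, so
#' a restored model predicts identically.
#'
#' @param model an \code{erna_logit}.
#' @param path file path.
#' @return \code{path} (write) / an \code{erna_logit} (read; prediction-only:
#'   fit diagnostics kept, training response and vcov not serialized).
#' @export
write_model <- function(model, path) {
  num <- function(v) sprintf("%.17g", v)
  rows <- c(
    paste("marks", paste(model$marks, collapse = ","), sep = "\t"),
    paste("lambda", num(model$lambda), sep = "\t"),
    paste("converged", model$converged, sep = "\t"),
    paste("iterations", model$iterations, sep = "\t"),
    paste("loglik", num(model$loglik), sep = "\t"),
    paste("n", model$n, sep = "\t"),
    paste("n_pos", model$n_pos, sep = "\t"),
    vapply(seq_along(model$coefficients), function(i) {
      paste("coef", names(model$coefficients)[i],
            num(model$coefficients[i]), sep = "\t")
    }, ""),
    vapply(seq_along(model$coefficients_raw), function(i) {
      paste("coef_raw", names(model$coefficients_raw)[i],
            num(model$coefficients_raw[i]), sep = "\t")
    }, ""),
    vapply(seq_along(model$center), function(i) {
      paste("center", names(model$center)[i], num(model$center[i]), sep = "\t")
    }, ""),
    vapply(seq_along(model$scale), function(i) {
      paste("scale", names(model$scale)[i], num(model$scale[i]), sep = "\t")
    }, "")
  )
  writeLines(c("#erna_logit model", rows), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  key <- vapply(parts, `[`, "", 1)
  get1 <- function(k) parts[[which(key == k)[1]]][2]
  named <- function(k) {
    idx <- which(key == k)
    setNames(as.numeric(vapply(parts[idx], `[`, "", 3)),
             vapply(parts[idx], `[`, "", 2))
  }
  coefs <- named("coef")
  structure(list(marks = strsplit(get1("marks"), ",", fixed = TRUE)[[1]],
                 coefficients = coefs, coefficients_raw = named("coef_raw"),
                 center = named("center"), scale = named("scale"),
                 lambda = as.numeric(get1("lambda")),
                 converged = as.logical(get1("converged")),
                 iterations = as.integer(get1("iterations")),
                 loglik = as.numeric(get1("loglik")),
                 n = as.integer(get1("n")), n_pos = as.integer(get1("n_pos"))),
            class = "erna_logit")
}

## ---- stage machinery ----

stage_order <- c("simulate", "catalog", "label", "train", "select",
                 "predict", "analyze")

need_file <- function(path, stage) {
  if (!file.exists(path)) {
    stop("stage '", stage, "': missing dependency file: ", path, call. = FALSE)
  }
  path
}

manifest_add <- function(outdir, stage, files) {
  mf <- file.path(outdir, "run_manifest.tsv")
  sums <- tools::md5sum(files)
  df <- data.frame(stage = stage, file = basename(files),
                   md5 = unname(sums), stringsAsFactors = FALSE)
  if (file.exists(mf)) {
    prev <- read_tsv_commented(mf)
    prev <- prev[prev$stage != stage, , drop = FALSE]
    df <- rbind(prev, df)
  }
  write_tsv_commented(df, mf)
  invisible(df)
}

data_paths <- function(config, outdir) {
  ddir <- file.path(outdir, "data")
  if (length(config$tracks)) {
    # real-data mode: all paths come from the config
    list(tracks = config$tracks, gro = config$gro_track,
         p300 = config$p300_peaks, k4me1 = config$h3k4me1_peaks,
         k4me3 = config$h3k4me3_peaks, k27ac = config$h3k27ac_peaks,
         genes = config$gene_table, mappability = config$mappability,
         expression = config$expression, simulated = FALSE)
  } else {
    mf <- file.path(ddir, "manifest.tsv")
    if (!file.exists(mf)) {
      stop("no track paths in config and no simulated data at ", ddir,
           " -- run the simulate stage first", call. = FALSE)
    }
    man <- read_tsv_commented(mf)
    grab <- function(role) {
      f <- man$file[man$role == role]
      if (!length(f)) NULL else file.path(ddir, f)
    }
    mark_rows <- grepl("^mark_reads:", man$role)
    tracks <- as.list(file.path(ddir, man$file[mark_rows]))
    names(tracks) <- sub("^mark_reads:", "", man$role[mark_rows])
    list(tracks = tracks, gro = grab("gro_reads"), p300 = grab("p300_peaks"),
         k4me1 = grab("h3k4me1_peaks"), k4me3 = grab("h3k4me3_peaks"),
         k27ac = grab("h3k27ac_peaks"), genes = grab("gene_table"),
         mappability = grab("mappability"), expression = grab("expression"),
         simulated = TRUE)
  }
}

#' Run one pipeline stage
#'
#' Stages: \code{simulate} (synthetic dataset), \code{catalog} (intergenic +
#' mappability filters, signal matrix), \code{label} (GRO-seq 2-means
#' labels), \code{train} (full-mark model + plain 10-fold CV reference),
#' \code{select} (nested-CV subset enumeration, top-model selection, mark
#' enrichment, m-vs-m+1 comparison), \code{predict} (best-subset model
#' probabilities for every enhancer), \code{analyze} (gene links, H3K27ac
#' status, four subgroups, expression comparisons). Each stage reads only
#' files produced by its dependencies (or named in the config), writes its
#' outputs under \code{outdir} and appends md5 digests to
#' \code{run_manifest.tsv}; a missing dependency is an error naming the
#' missing file. Stage RNG streams are derived from \code{config$seed} and
#' the stage name.
#'
#' @param name stage name.
#' @param config an \code{erna_config}.
#' @param outdir output directory.
#' @param synth a [synth_config()] for the simulate stage (defaults to
#'   \code{synth_config(seed = config$seed)}).
#' @return Invisibly, the vector of files the stage wrote.
#' @export
erna_run_stage <- function(name, config, outdir, synth = NULL) {
  name <- match.arg(name, stage_order)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  wrote <- switch(
    name,
    simulate = {
      synth <- synth %||% synth_config(seed = config$seed)
      res <- synth_dataset(synth, file.path(outdir, "data"))
      file.path(outdir, "data", res$manifest$file)
    },
    catalog = {
      dp <- data_paths(config, outdir)
      peaks_path <- if (identical(config$provenance, "P300")) dp$p300 else dp$k4me1
      provenance <- if (identical(config$provenance, "P300")) "P300" else "H3K4me1+me3-"
      peaks <- read_bed(need_file(peaks_path, name))
      genes <- read_gene_table(need_file(dp$genes, name))
      k4me3 <- read_bed(need_file(dp$k4me3, name))
      mapp <- read_mappability(need_file(dp$mappability, name))
      cat0 <- define_intergenic_enhancers(peaks, genes, k4me3,
                                          exclusion_bp = config$tss_exclusion_bp,
                                          window_half_bp = config$window_half_bp,
                                          provenance = provenance)
      catl <- apply_mappability_filter(cat0, mapp, config$mappability_min)
      message(sprintf("catalog: %d candidate peaks -> %d intergenic -> %d mappable",
                      nrow(peaks), nrow(cat0), nrow(catl)))
      tracks <- lapply(dp$tracks, function(f) read_bed(need_file(f, name)))
      gro <- read_bed(need_file(dp$gro, name), stranded = TRUE)
      signal <- compute_signal_matrix(catl, tracks, gro,
                                      pseudocount = config$pseudocount,
                                      log_base = config$log_base)
      write_tsv_commented(as.data.frame(catl), p("catalog.tsv"))
      write_signal_matrix(signal, p("signal.tsv"))
      c(p("catalog.tsv"), p("signal.tsv"))
    },
    label = {
      signal <- read_signal_matrix(need_file(p("signal.tsv"), name))
      labels <- label_enhancers(signal)
      message(sprintf("labels: %d positive, %d negative, %d ambiguous",
                      sum(labels$label == "positive"),
                      sum(labels$label == "negative"),
                      sum(labels$label == "ambiguous")))
      write_tsv_commented(as.data.frame(labels), p("labels.tsv"))
      p("labels.tsv")
    },
    train = {
      signal <- read_signal_matrix(need_file(p("signal.tsv"), name))
      labels <- read_labels(need_file(p("labels.tsv"), name))
      fit <- erna_logit(signal, labels, lambda = config$ridge)
      write_model(fit, p("model_full.tsv"))
      cvres <- plain_cv_evaluate(signal, labels, colnames(signal$x),
                                 k = config$folds,
                                 seed = derive_seed(config$seed, "train"),
                                 lambda = config$ridge)
      write_tsv_commented(cvres, p("full_model_cv.tsv"))
      c(p("model_full.tsv"), p("full_model_cv.tsv"))
    },
    select = {
      signal <- read_signal_matrix(need_file(p("signal.tsv"), name))
      labels <- read_labels(need_file(p("labels.tsv"), name))
      full_cv <- read_tsv_commented(need_file(p("full_model_cv.tsv"), name))
      plan <- make_cv_plan(labels, k = config$folds, inner_k = config$inner_folds,
                           seed = derive_seed(config$seed, "select"))
      marks <- colnames(signal$x)
      files <- character()
      results <- list()
      for (m in seq_len(min(config$max_subset_size, length(marks)))) {
        res <- nested_cv_evaluate(signal, labels, enumerate_subsets(marks, m),
                                  plan, top_n_inner = config$top_n_inner,
                                  lambda = config$ridge)
        results[[m]] <- res
        f <- p(sprintf("subset_results_m%d.tsv", m))
        write_tsv_commented(as.data.frame(res), f)
        files <- c(files, f)
        message(sprintf("select: m=%d best %s (AUC %.3f)", m,
                        res$subset[1], res$mean_auc[1]))
      }
      mtop <- length(results)
      report <- select_top_models(results[[mtop]], rule = "top_fraction",
                                  fraction = config$top_fraction)
      write_tsv_commented(report$selected[, c("subset", "m", "mean_auc", "mean_mcc")],
                          p("selection.tsv"))
      enr <- if (nrow(report$selected)) {
        do.call(rbind, lapply(marks, function(mk) {
          if (mk %in% unlist(strsplit(report$results$subset, "+", fixed = TRUE))) {
            mark_enrichment(report, mk)
          }
        }))
      } else {
        data.frame(mark = character(), k = integer(), K_pop = integer(),
                   n = integer(), N = integer(), p = numeric())
      }
      write_tsv_commented(enr, p("enrichment.tsv"))
      cmp <- if (mtop >= 2) {
        do.call(rbind, lapply(seq_len(mtop - 1L), function(m) {
          cc <- compare_m_performance(results[[m]], results[[m + 1L]])
          data.frame(m = m, best_m = cc$best_m, best_m_plus_1 = cc$best_m_plus_1,
                     p = cc$p.value, stringsAsFactors = FALSE)
        }))
      } else data.frame(m = integer(), best_m = character(),
                        best_m_plus_1 = character(), p = numeric())
      write_tsv_commented(cmp, p("m_comparison.tsv"))
      # refit the best subset on all labeled data for downstream prediction
      best_marks <- strsplit(results[[mtop]]$subset[1], "+", fixed = TRUE)[[1]]
      best_fit <- erna_logit(signal, labels, marks = best_marks,
                             lambda = config$ridge)
      write_model(best_fit, p("model_best.tsv"))
      c(files, p("selection.tsv"), p("enrichment.tsv"), p("m_comparison.tsv"),
        p("model_best.tsv"))
    },
    predict = {
      signal <- read_signal_matrix(need_file(p("signal.tsv"), name))
      model <- read_model(need_file(p("model_best.tsv"), name))
      prob <- predict(model, signal)
      pred <- data.frame(id = rownames(signal$x),
                         probability = prob,
                         call = ifelse(prob >= 0.5, "positive", "negative"),
                         stringsAsFactors = FALSE)
      write_tsv_commented(pred, p("predictions.tsv"))
      p("predictions.tsv")
    },
    analyze = {
      dp <- data_paths(config, outdir)
      catl <- read_catalog(need_file(p("catalog.tsv"), name))
      labels <- read_labels(need_file(p("labels.tsv"), name))
      pred <- read_tsv_commented(need_file(p("predictions.tsv"), name))
      genes <- read_gene_table(need_file(dp$genes, name))
      expr <- read_expression(need_file(dp$expression, name))
      k27 <- read_bed(need_file(dp$k27ac, name))
      links <- assign_genes(catl, genes, max_dist = config$gene_assign_max_bp)
      write_tsv_commented(links, p("links.tsv"))
      k27_status <- classify_h3k27ac(catl, k27, dist = config$k27ac_dist_bp)
      measured <- setNames(labels$label, labels$id)
      predicted <- setNames(pred$call, pred$id)
      grp_meas <- subgroup_enhancers(measured, k27_status)
      grp_pred <- subgroup_enhancers(predicted, k27_status)
      grp_pred$subgroup <- sub("^eRNA", "p-eRNA", grp_pred$subgroup)
      write_tsv_commented(grp_meas, p("subgroups_measured.tsv"))
      write_tsv_commented(grp_pred, p("subgroups_predicted.tsv"))
      cmp_m <- compare_expression(grp_meas, links, expr)
      cmp_p <- compare_expression(grp_pred, links, expr)
      write_tsv_commented(cmp_m$tests, p("expression_tests_measured.tsv"))
      write_tsv_commented(cmp_p$tests, p("expression_tests_predicted.tsv"))
      c(p("links.tsv"), p("subgroups_measured.tsv"), p("subgroups_predicted.tsv"),
        p("expression_tests_measured.tsv"), p("expression_tests_predicted.tsv"))
    }
  )
  manifest_add(outdir, name, wrote)
  invisible(wrote)
}

read_labels <- function(path) {
  x <- read_tsv_commented(path,
                          colClasses = c("character", "character", "numeric",
                                         "numeric", "character", "character"))
  class(x) <- c("erna_labels", "data.frame")
  x
}

read_catalog <- function(path) {
  x <- read_tsv_commented(path)
  x$id <- as.character(x$id)
  class(x) <- c("enhancer_catalog", "data.frame")
  x
}

## plain stratified K-fold CV of one mark set (the nested machinery reduces
## to this when there is a single candidate subset)
plain_cv_evaluate <- function(signal, labels, marks, k = 10L, seed = 1L,
                              lambda = 1e-6) {
  plan <- make_cv_plan(labels, k = k, inner_k = 2L, seed = seed)
  x <- signal$x[match(plan$ids, rownames(signal$x)), marks, drop = FALSE]
  scores <- t(vapply(seq_len(k), function(ko) {
    fit_score(x, plan$y, which(plan$fold != ko), which(plan$fold == ko),
              lambda, want_mcc = TRUE)
  }, c(auc = 0, mcc = 0)))
  data.frame(fold = seq_len(k), auc = scores[, "auc"], mcc = scores[, "mcc"])
}

#' Run the whole pipeline end to end
#'
#' Runs \code{simulate} (skipped when the config names real track paths),
#' then \code{catalog}, \code{label}, \code{train}, \code{select},
#' \code{predict} and \code{analyze}. One command reproduces the entire
#' synthetic experiment deterministically: re-running with the same seed
#' yields byte-identical outputs (verifiable from the md5 digests in
#' \code{run_manifest.tsv}).
#'
#' @inheritParams erna_run_stage
#' @return Invisibly, the run manifest data.frame.
#' @export
erna_run_all <- function(config, outdir, synth = NULL) {
  stages <- stage_order
  if (length(config$tracks)) stages <- setdiff(stages, "simulate")
  for (s in stages) erna_run_stage(s, config, outdir, synth = synth)
  invisible(read_tsv_commented(file.path(outdir, "run_manifest.tsv")))
}
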