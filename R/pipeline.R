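# Pipeline orchestration: ingest -> featurize -> select -> screen ->
# evaluate, as a configured, logged run.  Age is excluded from ML feature
# matrices by default (confounders bias the AUC) but always enters the
# logistic-regression adjustment.

#' Pipeline run configuration
#'
#' @param input either `list(kind = "synthetic", config = cohort_config())`
#'   or `list(kind = "dir", path = ..., manifest = ...)` — exactly one
#'   source.
#' @param model feature-group mask name (see [feature_mask()]).
#' @param k top-k size for IG-based masks.
#' @param params [svm_params()].
#' @param out_dir output directory (`NULL` = nothing written).
#' @param seed integer seed controlling simulation and any stochastic step.
#' @return List of class `ld_run_config`.
#' @export
run_config <- function(input = list(kind = "synthetic", config = cohort_config()),
                       model = "top-combined-1000", k = 1000L,
                       params = svm_params(), out_dir = NULL, seed = 1L) {
  stopifnot(input$kind %in% c("synthetic", "dir"), k >= 1)
  structure(list(input = input, model = model, k = as.integer(k),
                 params = params, out_dir = out_dir, seed = as.integer(seed)),
            class = "ld_run_config")
}

#' Run the full diagnostic pipeline
#'
#' Stages: load or simulate transcripts; build the 23-feature table and the
#' n-gram table; screen features (summary-table and MLR CSVs); apply the
#' configured feature mask; evaluate the SVM with leave-pair-out CV.
#' Outputs are pure functions of (input, config, seed).
#'
#' @param config an [run_config()] object.
#' @return List of class `ld_run_report`: `n_subjects`, `feature_table`,
#'   `ngram_table`, `screen`, `mlr`, `selection`, `lpocv`, `log`.
#' @export
run_pipeline <- function(config = run_config()) {
  log_lines <- c(sprintf("lingdx %s | seed %d | model %s",
                         as.character(utils::packageVersion("lingdx")),
                         config$seed, config$model))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (config$input$kind == "synthetic") {
    cohort <- stage("simulate",
                    generate_cohort(config$input$config, seed = config$seed))
    transcripts <- cohort$transcripts
    parses <- cohort$parses
  } else {
    if (!dir.exists(config$input$path))
      stop("input directory not found: ", config$input$path)
    transcripts <- stage("ingest",
                         read_chat_dir(config$input$path,
                                       manifest = config$input$manifest))
    parses <- stage("parse", load_parses(config$input$path, transcripts))
  }
  log_lines <- c(log_lines, sprintf("subjects: %d", length(transcripts)))

  ft <- stage("featurize", build_feature_table(transcripts, parses))
  nt <- stage("ngrams", build_ngram_table(transcripts))

  scr <- stage("screen", screen_features(ft))
  sig <- scr$feature[scr$p < 0.05]
  mlr <- stage("mlr", tryCatch(
    mlr_adjusted(ft, intersect(c("reduced_sentences", "mlu", "trailing_off"),
                               names(ft))),
    error = function(e) NULL))

  X23 <- as.matrix(ft[, intersect(feature_names_23(), names(ft)), drop = FALSE])
  Xng <- as.matrix(nt$counts)
  X <- cbind(X23, Xng)
  labels <- ft$group
  sel <- stage("select",
               feature_mask(config$model, colnames(X),
                            labels = labels, x = X, k = config$k))
  Xsel <- X[, sel, drop = FALSE]
  cv <- stage("evaluate", lpocv(Xsel, labels, params = config$params))
  log_lines <- c(log_lines,
                 sprintf("features: %d selected of %d", length(sel), ncol(X)),
                 sprintf("AUC %.4f (sd %.4f)", cv$A, cv$sd))

  report <- structure(list(n_subjects = length(transcripts),
                           feature_table = ft, ngram_table = nt,
                           screen = scr, significant = sig, mlr = mlr,
                           selection = sel, lpocv = cv, log = log_lines),
                      class = "ld_run_report")
  if (!is.null(config$out_dir)) write_run_report(report, config)
  report
}

load_parses <- function(path, transcripts) {
  lapply(transcripts, function(t) {
    tf <- file.path(path, paste0(t$subject_id, ".trees"))
    df <- file.path(path, paste0(t$subject_id, ".deps"))
    list(trees = if (file.exists(tf)) read_trees(tf) else list(),
         deps = if (file.exists(df)) read_deps(df) else list())
  })
}

write_run_report <- function(report, config) {
  d <- config$out_dir
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(report$feature_table, file.path(d, "features.csv"))
  write_ngram_table(report$ngram_table, file.path(d, "ngrams"))
  utils::write.csv(report$screen, file.path(d, "screen.csv"), row.names = FALSE)
  if (!is.null(report$mlr))
    utils::write.csv(report$mlr$coefficients, file.path(d, "mlr.csv"),
                     row.names = FALSE)
  jsonlite::write_json(list(A = report$lpocv$A, sd = report$lpocv$sd,
                            folds = nrow(report$lpocv$pairs),
                            n_subjects = report$n_subjects,
                            model = config$model, seed = config$seed),
                       file.path(d, "lpocv.json"), auto_unbox = TRUE,
                       digits = NA)
  writeLines(report$log, file.path(d, "run.log"))
  invisible(d)
}

#' @export
print.ld_run_report <- function(x, ...) {
  cat(paste(x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `featurize`, `stats`, `evaluate`, `all` — see
#' `lingdx_cli(c("all", "--help"))`.  Used by the `exec/lingdx` script.
#'
#' @param args character vector of command-line arguments.
#' @return Invisibly, the run report (where applicable).
#' @export
lingdx_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: lingdx <simulate|featurize|stats|evaluate|all> [options]",
    "  --input DIR     read a cohort directory (.cha/.trees/.deps + manifest.csv)",
    "  --out DIR       output directory (default lingdx-out)",
    "  --model NAME    feature mask (default top-combined-1000)",
    "  --k N           top-k size (default 1000)",
    "  --C X --gamma X SVM hyperparameters",
    "  --n N           synthetic subjects per group (default 99)",
    "  --seed N        RNG seed (default 1)", sep = "\n")
  if (!length(args) || args[1] %in% c("-h", "--help")) { cat(usage, "\n"); return(invisible(NULL)) }
  cmd <- args[1]
  opt <- function(name, default) {
    i <- which(args == paste0("--", name))
    if (length(i) && i < length(args)) args[i + 1L] else default
  }
  seed <- as.integer(opt("seed", "1"))
  out <- opt("out", "lingdx-out")
  n <- as.integer(opt("n", "99"))
  model <- opt("model", "top-combined-1000")
  k <- as.integer(opt("k", "1000"))
  params <- svm_params(C = as.numeric(opt("C", svm_params()$C)),
                       gamma = as.numeric(opt("gamma", svm_params()$gamma)))
  input_dir <- opt("input", NA)
  input <- if (is.na(input_dir))
    list(kind = "synthetic", config = cohort_config(n_per_group = n))
  else
    list(kind = "dir", path = input_dir,
         manifest = if (file.exists(file.path(input_dir, "manifest.csv")))
           file.path(input_dir, "manifest.csv") else NULL)

  if (cmd == "simulate") {
    generate_cohort(cohort_config(n_per_group = n), seed = seed, dir = out)
    cat("cohort written to ", out, "\n", sep = "")
    return(invisible(NULL))
  }
  cfg <- run_config(input = input, model = model, k = k, params = params,
                    out_dir = out, seed = seed)
  report <- run_pipeline(cfg)
  if (cmd %in% c("evaluate", "all"))
    cat(jsonlite::toJSON(list(A = report$lpocv$A, sd = report$lpocv$sd,
                              folds = nrow(report$lpocv$pairs)),
                         auto_unbox = TRUE, digits = NA), "\n")
  invisible(report)
}
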