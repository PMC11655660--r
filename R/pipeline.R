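#' Assemble and validate a full run configuration
#'
#' Bundles the stage configurations for an end-to-end run. Stage
#' configurations may be given as ready-made objects ([sim_config()],
#' [irasa_config()], [decode_config()]) or as plain lists, in which case
#' every required key must be present explicitly — a missing key raises
#' an error naming it rather than silently falling back to a default.
#'
#' @param sim a [sim_config], or a path prefix to an epoch set written
#'   by [write_epoch_set()].
#' @param irasa an [irasa_config] or a complete plain list of its
#'   fields.
#' @param decode a [decode_config] or a complete plain list of its
#'   fields.
#' @param inference list with `K` (permutation iterations) and `alpha`.
#' @param window analysis window `c(start, end)` seconds.
#' @param thresholds [rejection_thresholds()].
#' @param contrasts subset of `c("demand", "content")`.
#' @param content_easy_only restrict content decoding to easy trials.
#' @param geometry compute the condition-geometry embeddings.
#' @param write_features also write the (large) per-trial feature TSV.
#' @param out_dir output directory.
#' @param seed master seed; all stage seeds derive from it.
#' @return an object of class `run_config`.
#' @export
run_config <- function(sim,
                       irasa = irasa_config(),
                       decode = decode_config(),
                       inference = list(K = 1000, alpha = 0.05),
                       window = c(0.3, 1.5),
                       thresholds = rejection_thresholds(),
                       contrasts = c("demand", "content"),
                       content_easy_only = FALSE,
                       geometry = TRUE,
                       write_features = FALSE,
                       out_dir = "irasadecode-out",
                       seed = 1) {
  coerce <- function(obj, ctor, cls, req) {
    if (inherits(obj, cls)) return(obj)
    if (!is.list(obj)) stop_invalid("expected a %s or a list", cls)
    missing_keys <- setdiff(req, names(obj))
    if (length(missing_keys)) {
      stop_invalid("configuration missing required key(s): %s",
                   paste(missing_keys, collapse = ", "))
    }
    do.call(ctor, obj[intersect(names(obj), names(formals(ctor)))])
  }
  irasa <- coerce(irasa, irasa_config, "irasa_config",
                  c("h_set", "freq_grid", "fit_range", "bands",
                    "broadband_range"))
  decode <- coerce(decode, decode_config, "decode_config",
                   c("n_folds", "n_reps", "pca_variance", "pseudo_size"))
  if (!is.character(sim) && !inherits(sim, "sim_config")) {
    stop_invalid("`sim` must be a sim_config or an epoch-set path prefix")
  }
  if (is.character(sim) && !file.exists(paste0(sim, ".json"))) {
    stop_invalid("epoch-set sidecar not found: %s.json", sim)
  }
  if (!all(contrasts %in% c("demand", "content")) || !length(contrasts)) {
    stop_invalid("contrasts must be a non-empty subset of demand, content")
  }
  if (is.null(inference$K) || inference$K < 1) {
    stop_invalid("inference$K must be >= 1")
  }
  structure(list(sim = sim, irasa = irasa, decode = decode,
                 inference = inference, window = window,
                 thresholds = thresholds, contrasts = contrasts,
                 content_easy_only = content_easy_only,
                 geometry = geometry, write_features = write_features,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

decode_one_contrast <- function(feats, contrast, cfg, easy_only = FALSE) {
  rows <- list()
  labels <- feats[[1]]$labels
  subjects <- sort(unique(labels$subject))
  if (contrast == "demand") {
    groups <- unique(labels[, c("task", "content")])
    group_id <- function(g) paste(g$task, g$content, sep = "-")
    sel_group <- function(lab, g) lab$task == g$task & lab$content == g$content
    class_col <- "demand"
    class_levels <- demand_levels()
  } else {
    groups <- unique(labels[, c("task"), drop = FALSE])
    group_id <- function(g) g$task
    sel_group <- function(lab, g) lab$task == g$task &
      (!easy_only | lab$demand == "easy")
    class_col <- "content"
    class_levels <- content_levels()
  }
  for (sig in names(feats)) {
    sf <- feats[[sig]]
    for (gi in seq_len(nrow(groups))) {
      g <- groups[gi, , drop = FALSE]
      for (si in seq_along(subjects)) {
        sel <- sf$labels$subject == subjects[si] & sel_group(sf$labels, g)
        y <- factor(sf$labels[[class_col]][sel], levels = class_levels)
        dcfg <- cfg$decode
        dcfg$seed <- derive_seed(cfg$seed, match(sig, signal_names()), gi, si)
        res <- decode_within(sf$x[sel, , drop = FALSE], y, dcfg)
        rows[[length(rows) + 1]] <- data.frame(
          subject = subjects[si], contrast = contrast,
          subtask = group_id(g), signal = sig, auc = res$auc,
          n_pseudotrials = res$n_pseudotrials, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) epoched data, applies peak-to-peak rejection,
#' evoked subtraction and windowing, extracts the six IRASA signals,
#' decodes the requested contrasts per subject x subtask x signal,
#' tests the group AUCs against chance with BH-FDR correction, builds
#' cross-task generalization matrices and group activation patterns for
#' the demand contrast, optionally computes Procrustes-aligned condition
#' geometry, and writes every stage product as a tidy TSV plus a JSON
#' run manifest. Rerunning with the same configuration reproduces all
#' numeric outputs exactly.
#'
#' @param config a [run_config].
#' @return invisibly, a list with all in-memory stage results and the
#'   paths written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(cfg$out_dir, name)
  paths <- character(0)

  # --- data ------------------------------------------------------------
  if (inherits(cfg$sim, "sim_config")) {
    sim <- cfg$sim
    sim$seed <- derive_seed(cfg$seed, 11)
    gen <- gen_epoch_set(sim)
    epochs <- gen$epochs
    truth <- gen$truth
    write_ground_truth(truth, out("ground_truth.json"))
    paths <- c(paths, out("ground_truth.json"))
  } else {
    epochs <- read_epoch_set(cfg$sim)
    truth <- NULL
  }

  # --- preprocessing ---------------------------------------------------
  rej <- reject_epochs(epochs, cfg$thresholds)
  write_rejection_report(rej$report, out("rejection_report.tsv"))
  paths <- c(paths, out("rejection_report.tsv"))
  clean <- subtract_evoked(rej$epochs)
  windowed <- crop_window(clean, cfg$window[1], cfg$window[2])

  # --- spectral features ----------------------------------------------
  feats <- spectral_features(windowed, cfg$irasa)
  if (cfg$write_features) {
    write_feature_table(feats, out("features.tsv"))
    paths <- c(paths, out("features.tsv"))
  }

  # --- decoding --------------------------------------------------------
  results <- do.call(rbind, lapply(cfg$contrasts, function(ct) {
    decode_one_contrast(feats, ct, cfg, cfg$content_easy_only)
  }))
  utils::write.table(results, out("decoding.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(paths, out("decoding.tsv"))

  # --- group statistics ------------------------------------------------
  stats_rows <- list()
  for (ct in unique(results$contrast)) {
    sub <- results[results$contrast == ct, ]
    combos <- unique(sub[, c("subtask", "signal")])
    ps <- numeric(nrow(combos))
    for (i in seq_len(nrow(combos))) {
      aucs <- sub$auc[sub$subtask == combos$subtask[i] &
                      sub$signal == combos$signal[i]]
      ht <- if (length(aucs) >= 2) group_auc_test(aucs, 0.5, "one") else
        list(t = NA_real_, p = NA_real_, mean = mean(aucs), n = length(aucs))
      ps[i] <- ht$p
      stats_rows[[length(stats_rows) + 1]] <- data.frame(
        analysis = "decoding", contrast = ct,
        subtask = combos$subtask[i], signal = combos$signal[i],
        statistic = ht$t, mean_auc = ht$mean, p_raw = ht$p,
        p_fdr = NA_real_, n = ht$n, tail = "one",
        stringsAsFactors = FALSE)
    }
    if (!anyNA(ps)) {
      adj <- bh_fdr(ps)
      k <- length(stats_rows)
      for (i in seq_len(nrow(combos))) {
        stats_rows[[k - nrow(combos) + i]]$p_fdr <- adj[i]
      }
    }
  }
  stats_tab <- do.call(rbind, stats_rows)
  utils::write.table(stats_tab, out("group_stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(paths, out("group_stats.tsv"))

  # --- cross-task generalization (demand) ------------------------------
  gen_tabs <- NULL
  labels <- feats[[1]]$labels
  subtasks <- unique(labels[, c("task", "content")])
  if ("demand" %in% cfg$contrasts && nrow(subtasks) >= 2) {
    subjects <- sort(unique(labels$subject))
    gen_rows <- list()
    for (sig in names(feats)) {
      sf <- feats[[sig]]
      acc <- NULL
      for (si in seq_along(subjects)) {
        xs <- list(); ys <- list()
        for (gi in seq_len(nrow(subtasks))) {
          g <- subtasks[gi, ]
          sel <- sf$labels$subject == subjects[si] &
            sf$labels$task == g$task & sf$labels$content == g$content
          xs[[paste(g$task, g$content, sep = "-")]] <-
            sf$x[sel, , drop = FALSE]
          ys[[length(ys) + 1]] <- factor(sf$labels$demand[sel],
                                         levels = demand_levels())
        }
        dcfg <- cfg$decode
        dcfg$seed <- derive_seed(cfg$seed, 77, match(sig, signal_names()), si)
        M <- generalization_matrix(xs, ys, dcfg)
        acc <- if (is.null(acc)) M else acc + M
      }
      acc <- acc / length(subjects)
      gen_rows[[sig]] <- data.frame(
        signal = sig,
        train = rep(rownames(acc), ncol(acc)),
        test = rep(colnames(acc), each = nrow(acc)),
        auc = as.vector(acc), stringsAsFactors = FALSE)
    }
    gen_tabs <- do.call(rbind, gen_rows)
    utils::write.table(gen_tabs, out("generalization.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, out("generalization.tsv"))
  }

  # --- activation patterns (demand) ------------------------------------
  group_patterns <- NULL
  if ("demand" %in% cfg$contrasts) {
    group_patterns <- list()
    subjects <- sort(unique(labels$subject))
    for (sig in names(feats)) {
      sf <- feats[[sig]]
      pats <- list()
      for (si in seq_along(subjects)) {
        for (gi in seq_len(nrow(subtasks))) {
          g <- subtasks[gi, ]
          sel <- sf$labels$subject == subjects[si] &
            sf$labels$task == g$task & sf$labels$content == g$content
          y <- factor(sf$labels$demand[sel], levels = demand_levels())
          dcfg <- cfg$decode
          dcfg$seed <- derive_seed(cfg$seed, 88, match(sig, signal_names()),
                                   gi, si)
          pats[[length(pats) + 1]] <-
            activation_pattern(sf$x[sel, , drop = FALSE], y, dcfg)
        }
      }
      group_patterns[[paste0(sig, "/demand")]] <- aggregate_patterns(pats)
    }
    write_pattern_table(group_patterns, out("patterns.tsv"))
    paths <- c(paths, out("patterns.tsv"))
  }

  # --- condition geometry ----------------------------------------------
  embeddings <- NULL
  tasks_present <- unique(labels$task)
  conds_per_task <- length(unique(labels$content)) *
    length(unique(labels$demand))
  if (cfg$geometry && conds_per_task >= 3) {
    embeddings <- list()
    subjects <- sort(unique(labels$subject))
    for (sig in names(feats)) {
      sf <- feats[[sig]]
      per_subject <- list()
      for (si in seq_along(subjects)) {
        per_task <- list()
        for (tk in tasks_present) {
          sel <- sf$labels$subject == subjects[si] & sf$labels$task == tk
          cm <- condition_means(sf$x[sel, , drop = FALSE],
                                sf$labels[sel, , drop = FALSE])
          rownames(cm) <- sub("^[^_]+_", "", rownames(cm))
          e <- embed_pca2(cm)
          per_task[[tk]] <- e
        }
        per_subject[[si]] <- average_aligned(per_task)
      }
      embeddings[[sig]] <- average_aligned(per_subject)
    }
    write_embedding_table(embeddings, out("embeddings.tsv"))
    paths <- c(paths, out("embeddings.tsv"))
  }

  # --- manifest --------------------------------------------------------
  manifest <- list(
    package = "irasadecode",
    version = tryCatch(as.character(utils::packageVersion("irasadecode")),
                       error = function(e) "dev"),
    seed = cfg$seed,
    contrasts = cfg$contrasts,
    window = cfg$window,
    irasa = unclass(cfg$irasa),
    decode = unclass(cfg$decode),
    n_epochs_in = n_epochs(epochs),
    n_epochs_rejected = n_epochs(epochs) - n_epochs(rej$epochs),
    outputs = basename(paths)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(epochs = epochs, truth = truth, features = feats,
                 decoding = results, stats = stats_tab,
                 generalization = gen_tabs, patterns = group_patterns,
                 embeddings = embeddings,
                 paths = c(paths, out("manifest.json"))))
}
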