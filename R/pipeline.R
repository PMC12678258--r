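# End-to-end pipeline: corpus -> encoder -> phrase funnel -> ball embedding
# vs Euclidean baseline -> attention relation matrix under the acyclicity
# constraint -> tangent-space clustering with k selection -> validation
# statistics -> framework comparison. One global seed is fanned out to
# per-stage streams; a fixed config + seed yields an identical report.

#' Planted study phrases and hierarchy for the default synthetic corpus
#'
#' 39 two-word indicator phrases in 4 topics (10/10/10/9, mirroring the
#' four indicator dimensions), each planted with total frequency >= 7 and
#' document spread >= 10 so the screening funnel can retain them, plus a
#' phrase-level hierarchy (each topic's first phrase parents the rest of
#' its topic; topic heads hang off the first head).
#'
#' @param n_decoys additional low-frequency decoy phrases that the funnel
#'   must reject (default 25).
#' @return list with `phrases` (data.frame for [synthetic_spec()]),
#'   `phrase_hierarchy` (data.frame parent/child phrase text), and
#'   `topic_hierarchy`.
#' @export
default_study_phrases <- function(n_decoys = 25L) {
  topics <- c("medical", "spatial", "services", "ecology")
  sizes <- c(10L, 10L, 9L, 10L)
  nouns <- list(
    medical = c("triage surge", "telehealth uplink", "vaccine logistics",
                "isolation wards", "sentinel surveillance", "oxygen reserve",
                "ambulance routing", "pharmacy stockpile", "testing cadence",
                "infection audit"),
    spatial = c("modular shelters", "ventilated atria", "transit redundancy",
                "walkable buffers", "utility hardening", "broadband mesh",
                "convertible plazas", "supply corridors", "microgrid nodes",
                "evacuation grid"),
    services = c("mutual aid", "caregiver registry", "food vouchers",
                 "counseling hotline", "literacy outreach", "volunteer roster",
                 "eldercare liaison", "childcare relief", "benefit navigation"),
    ecology = c("greenway access", "canopy equity", "stormwater basins",
                "habitat corridors", "air monitoring", "compost network",
                "waste triage", "pollinator verges", "watershed stewardship",
                "heat refugia"))
  rows <- list(); edges_p <- list()
  for (ti in seq_along(topics)) {
    ph <- nouns[[topics[ti]]][seq_len(sizes[ti])]
    # frequencies descend within a topic; all clear the funnel thresholds
    rows[[ti]] <- data.frame(
      phrase = ph,
      total_freq = 30L - 1L * seq_along(ph),
      doc_freq = 10L + (seq_along(ph) %% 2L),
      topic = topics[ti], stringsAsFactors = FALSE)
    edges_p[[ti]] <- data.frame(parent = ph[1], child = ph[-1],
                                stringsAsFactors = FALSE)
  }
  phrases <- do.call(rbind, rows)
  heads <- vapply(seq_along(topics), function(ti) nouns[[topics[ti]]][1],
                  character(1))
  phrase_hierarchy <- rbind(do.call(rbind, edges_p),
                            data.frame(parent = heads[1], child = heads[-1],
                                       stringsAsFactors = FALSE))
  if (n_decoys > 0) {
    decoys <- data.frame(
      phrase = paste0("decoy", sprintf("%02d", seq_len(n_decoys)),
                      " filler", sprintf("%02d", seq_len(n_decoys))),
      total_freq = 3L + (seq_len(n_decoys) %% 3L),
      doc_freq = 2L + (seq_len(n_decoys) %% 2L),
      topic = "noise", stringsAsFactors = FALSE)
    phrases <- rbind(phrases, decoys)
  }
  list(phrases = phrases,
       phrase_hierarchy = phrase_hierarchy,
       topic_hierarchy = data.frame(parent = "medical",
                                    child = c("spatial", "services",
                                              "ecology"),
                                    stringsAsFactors = FALSE))
}

#' Pipeline configuration
#'
#' All arguments have working defaults: a 230-document synthetic corpus
#' with the [default_study_phrases()] planting, a 64-dimensional hash
#' encoder, the default screening thresholds, 2-dimensional embeddings,
#' 8-head attention, k scanned over 3..7, and synthetic 5-expert and
#' 15-expert rater panels.
#'
#' @param seed global integer seed.
#' @param corpus_path optional JSONL/CSV corpus to use instead of the
#'   synthetic default.
#' @param n_docs synthetic corpus size.
#' @param encoder_d encoder dimension.
#' @param train_encoder fit a trainable token-embedding encoder with the
#'   contrastive objective instead of using the hash encoder directly.
#' @param screening a [screening_config()].
#' @param sensitivity_thresholds relevance thresholds to scan.
#' @param embed_dim,embed_iters,embed_lr ball/baseline embedding controls.
#' @param attention_heads,attention_dk attention geometry.
#' @param k_range candidate cluster counts.
#' @param rater_agreement probability for the synthetic panels.
#' @param membership_path membership CSV (default: packaged fixture).
#' @param stages named logical vector enabling optional stages
#'   (`sensitivity`, `compare`, `relations`, `clustering`, `validation`,
#'   `framework`).
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L, corpus_path = NULL, n_docs = 230L,
                            encoder_d = 64L, train_encoder = FALSE,
                            screening = screening_config(),
                            sensitivity_thresholds = c(0.55, 0.60, 0.65,
                                                       0.70, 0.75),
                            embed_dim = 2L, embed_iters = 600L,
                            embed_lr = 0.05, attention_heads = 8L,
                            attention_dk = 64L, k_range = 3:7,
                            rater_agreement = 0.85,
                            membership_path = NULL,
                            stages = c(sensitivity = TRUE, compare = TRUE,
                                       relations = TRUE, clustering = TRUE,
                                       validation = TRUE, framework = TRUE)) {
  structure(list(seed = as.integer(seed), corpus_path = corpus_path,
                 n_docs = as.integer(n_docs), encoder_d = as.integer(encoder_d),
                 train_encoder = isTRUE(train_encoder), screening = screening,
                 sensitivity_thresholds = sensitivity_thresholds,
                 embed_dim = as.integer(embed_dim),
                 embed_iters = as.integer(embed_iters), embed_lr = embed_lr,
                 attention_heads = as.integer(attention_heads),
                 attention_dk = as.integer(attention_dk), k_range = k_range,
                 rater_agreement = rater_agreement,
                 membership_path = membership_path, stages = stages),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the
#' `screening` key holds [screening_config()] arguments.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$screening)) y$screening <- do.call(screening_config, y$screening)
  if (!is.null(y$stages)) y$stages <- unlist(y$stages)
  if (!is.null(y$k_range)) y$k_range <- do.call(seq, as.list(range(unlist(y$k_range))))
  do.call(pipeline_config, y)
}

stage_on <- function(cfg, name) isTRUE(cfg$stages[[name]] %||% TRUE)

#' Run the full indicator-mining pipeline
#'
#' Executes every enabled stage in order (preprocess, encode, extract and
#' screen, embed and compare spaces, relations with DAG enforcement,
#' tangent-space clustering with k selection, validation statistics,
#' framework comparison) and returns a report object. Deterministic for a
#' fixed config and seed.
#'
#' @param cfg a [pipeline_config()].
#' @return object of class `"pipeline_report"`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  seed <- cfg$seed
  study <- default_study_phrases()

  # --- corpus ---------------------------------------------------------
  if (!is.null(cfg$corpus_path)) {
    corp <- read_corpus(cfg$corpus_path)
    truth <- NULL
  } else {
    spec <- synthetic_spec(cfg$n_docs, vocab_size = 600,
                           planted_phrases = study$phrases,
                           topic_hierarchy = study$topic_hierarchy,
                           seed = derive_seed(seed, 1L))
    gen <- generate_corpus(spec)
    corp <- gen$corpus; truth <- gen$truth
  }
  seqs <- preprocess_corpus(corp)

  # --- encoder --------------------------------------------------------
  if (cfg$train_encoder) {
    tr <- train_contrastive(seqs,
                            cfg = training_config(batch_size = 16L,
                                                  epochs = 1L, lr = 0.05,
                                                  val_every = 5L,
                                                  seed = derive_seed(seed, 2L)),
                            aug = augmentation_spec(seed = derive_seed(seed, 3L)))
    enc <- tr$encoder; training_log <- tr$log
  } else {
    enc <- hash_encoder(d = cfg$encoder_d, seed = derive_seed(seed, 2L))
    training_log <- NULL
  }

  # --- phrase pool and funnel -----------------------------------------
  pool <- extract_ngrams(seqs, max_n = cfg$screening$max_words)
  pool <- tfidf_norm(pool, length(seqs))
  centroid <- domain_centroid(enc, seqs)
  pool <- add_relevance(pool, enc, centroid)
  pool <- specificity_index(pool, seqs)
  funnel <- screen(pool, cfg$screening, encoder = enc)
  retained <- funnel$retained$phase4

  sens <- NULL
  if (stage_on(cfg, "sensitivity") && length(retained))
    sens <- sensitivity_analysis(pool, cfg$sensitivity_thresholds,
                                 reference_set = retained,
                                 cfg = cfg$screening, encoder = enc)

  # --- embeddings and space comparison --------------------------------
  emb_cmp <- NULL; emb <- NULL; H <- NULL
  if (length(retained) >= 3) {
    phr_emb <- t(vapply(retained, phrase_embedding, numeric(enc$d),
                        encoder = enc, USE.NAMES = FALSE))
    nrm <- sqrt(rowSums(phr_emb^2)); nrm[nrm == 0] <- 1
    cosm <- (phr_emb %*% t(phr_emb)) / (nrm %o% nrm)
    delta <- 1 - cosm
    delta[delta < 1e-6] <- 1e-6
    diag(delta) <- 0
    delta <- (delta + t(delta)) / 2
    eh <- study$phrase_hierarchy
    keep <- eh$parent %in% retained & eh$child %in% retained
    if (any(keep))
      H <- hierarchy_edges(match(eh$parent[keep], retained),
                           match(eh$child[keep], retained))
    emb <- embed_ball(delta, H = H, dim = cfg$embed_dim,
                      seed = derive_seed(seed, 4L), iters = cfg$embed_iters,
                      lr = cfg$embed_lr)
    if (stage_on(cfg, "compare") && !is.null(H))
      emb_cmp <- compare_spaces(delta, H, dim = cfg$embed_dim,
                                seed = derive_seed(seed, 5L),
                                iters = cfg$embed_iters, lr = cfg$embed_lr)
  }

  # --- relation matrix -------------------------------------------------
  relations <- NULL
  if (stage_on(cfg, "relations") && !is.null(emb)) {
    pts <- tangent_project(emb)
    ap <- attention_params(d = ncol(pts), n_out = nrow(pts),
                           h = cfg$attention_heads, d_k = cfg$attention_dk,
                           seed = derive_seed(seed, 6L))
    C <- mhsa_relation_matrix(pts, ap)
    Cdag <- enforce_dag(C)
    relations <- list(C = Cdag, S = symmetrize(Cdag),
                      penalty_before = dag_penalty(C),
                      penalty_after = dag_penalty(Cdag))
  }

  # --- clustering ------------------------------------------------------
  clustering <- NULL
  if (stage_on(cfg, "clustering") && !is.null(emb) &&
      nrow(emb$coords) >= max(cfg$k_range)) {
    pts <- tangent_project(emb)
    clustering <- select_k(pts, phrases = retained, seqs = seqs,
                           k_range = cfg$k_range,
                           seed = derive_seed(seed, 7L))
  }

  # --- validation statistics ------------------------------------------
  validation <- NULL
  if (stage_on(cfg, "validation") && length(retained) >= 2) {
    panel3 <- generate_raters(length(retained), 3L,
                              agreement = cfg$rater_agreement,
                              seed = derive_seed(seed, 8L))
    panel5 <- generate_raters(length(retained), 5L,
                              agreement = cfg$rater_agreement,
                              seed = derive_seed(seed, 9L))
    groups <- rep(c("strict", "moderate", "voluntary"), length.out = 15L)
    panel15 <- generate_raters(length(retained), 15L,
                               agreement = cfg$rater_agreement,
                               seed = derive_seed(seed, 10L),
                               groups = groups)
    gm <- t(apply(panel15, 1, function(r) tapply(r, groups, mean)))
    validation <- list(
      kappa = panel_kappa(panel3),
      retained = likert_retention(panel5),
      mean_score = mean(panel15),
      npi_flags = npi_variance_flag(gm))
  }

  # --- framework comparison -------------------------------------------
  framework <- NULL
  if (stage_on(cfg, "framework")) {
    mt <- if (is.null(cfg$membership_path)) load_membership()
          else load_membership(cfg$membership_path)
    framework <- overlap_stats(mt)
  }

  structure(list(
    corpus_n = length(corp),
    truth = truth,
    funnel = funnel,
    sensitivity = sens,
    embedding = emb,
    hierarchy = H,
    space_comparison = if (is.null(emb_cmp)) NULL else
      emb_cmp[c("hfs_hyperbolic", "hfs_euclidean",
                "distortion_hyperbolic", "distortion_euclidean")],
    relations = relations,
    clustering = clustering,
    validation = validation,
    framework = framework,
    training_log = training_log,
    provenance = list(seed = seed,
                      config_hash = hash_string(jsonlite::toJSON(
                        cfg[setdiff(names(cfg), "screening")],
                        auto_unbox = TRUE, force = TRUE)),
                      package_version = as.character(
                        utils::packageVersion("resilmine")))),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> corpus N =", x$corpus_n, "\n")
  cat("  funnel:", paste(names(x$funnel$counts), x$funnel$counts,
                         sep = "=", collapse = " "), "\n")
  if (!is.null(x$space_comparison))
    cat(sprintf("  HFS hyperbolic %.3f vs euclidean %.3f; distortion %.3f vs %.3f\n",
                x$space_comparison$hfs_hyperbolic,
                x$space_comparison$hfs_euclidean,
                x$space_comparison$distortion_hyperbolic,
                x$space_comparison$distortion_euclidean))
  if (!is.null(x$clustering)) cat("  best k =", x$clustering$best_k, "\n")
  if (!is.null(x$validation))
    cat(sprintf("  panel kappa %.3f, mean expert score %.2f\n",
                x$validation$kappa, x$validation$mean_score))
  invisible(x)
}

report_json_body <- function(report) {
  list(
    schema_version = "1.0",
    corpus_n = report$corpus_n,
    funnel = list(counts = as.list(report$funnel$counts),
                  retained = report$funnel$retained$phase4),
    sensitivity = if (!is.null(report$sensitivity))
      as.data.frame(report$sensitivity),
    space_comparison = report$space_comparison,
    relations = if (!is.null(report$relations))
      list(penalty_before = report$relations$penalty_before,
           penalty_after = report$relations$penalty_after),
    clustering = if (!is.null(report$clustering))
      list(best_k = report$clustering$best_k,
           table = report$clustering$table),
    validation = if (!is.null(report$validation))
      list(kappa = report$validation$kappa,
           n_retained = sum(report$validation$retained),
           mean_score = report$validation$mean_score,
           n_flagged = sum(report$validation$npi_flags)),
    framework = if (!is.null(report$framework))
      report$framework[c("n", "frameworks", "novel_count", "novel_fraction")],
    provenance = report$provenance)
}

#' Emit a pipeline report to disk
#'
#' Writes a JSON report (stable field order), a CSV bundle, and a
#' markdown summary whose every number appears in the JSON report.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory.
#' @param formats subset of `c("json", "csv", "markdown")`.
#' @return the directory, invisibly.
#' @export
emit_report <- function(report, dir,
                        formats = c("json", "csv", "markdown")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  body <- report_json_body(report)
  if ("json" %in% formats)
    jsonlite::write_json(body, file.path(dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  if ("csv" %in% formats) {
    write_funnel_report(report$funnel, dir)
    if (!is.null(report$sensitivity))
      utils::write.csv(report$sensitivity,
                       file.path(dir, "sensitivity.csv"), row.names = FALSE)
    if (!is.null(report$clustering)) {
      utils::write.csv(report$clustering$table,
                       file.path(dir, "cluster_metrics.csv"),
                       row.names = FALSE)
      best <- report$clustering$results[[
        match(report$clustering$best_k, report$clustering$table$k)]]
      utils::write.csv(data.frame(id = report$funnel$retained$phase4,
                                  cluster = best$labels),
                       file.path(dir, "cluster_labels.csv"),
                       row.names = FALSE)
    }
    if (!is.null(report$embedding))
      write_embedding(report$embedding, file.path(dir, "embedding.csv"),
                      ids = report$funnel$retained$phase4)
    if (!is.null(report$relations)) {
      write_relation_matrix(report$relations$C, file.path(dir, "relations_C.csv"),
                            ids = report$funnel$retained$phase4)
      write_relation_matrix(report$relations$S, file.path(dir, "relations_S.csv"),
                            ids = report$funnel$retained$phase4)
    }
    if (!is.null(report$framework))
      utils::write.csv(report$framework$frameworks,
                       file.path(dir, "framework_overlap.csv"),
                       row.names = FALSE)
  }
  if ("markdown" %in% formats) {
    md <- c("# Indicator mining report", "",
            paste0("Corpus: ", report$corpus_n, " documents"), "",
            "## Screening funnel", "")
    md <- c(md, paste0("- ", names(report$funnel$counts), ": ",
                       report$funnel$counts))
    if (!is.null(report$space_comparison)) {
      sc <- report$space_comparison
      md <- c(md, "", "## Embedding comparison", "",
              sprintf("- HFS: hyperbolic %.4f, euclidean %.4f",
                      sc$hfs_hyperbolic, sc$hfs_euclidean),
              sprintf("- Distortion: hyperbolic %.4f, euclidean %.4f",
                      sc$distortion_hyperbolic, sc$distortion_euclidean))
    }
    if (!is.null(report$clustering))
      md <- c(md, "", "## Clustering", "",
              paste0("- best k = ", report$clustering$best_k))
    if (!is.null(report$validation))
      md <- c(md, "", "## Validation", "",
              sprintf("- panel kappa: %.4f", report$validation$kappa),
              sprintf("- mean expert score: %.4f",
                      report$validation$mean_score))
    writeLines(md, file.path(dir, "summary.md"))
  }
  invisible(dir)
}
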