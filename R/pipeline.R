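#' End-to-end run configuration
#'
#' Collects the file inputs, docking sites, protocol and model options of
#' a full prediction run: dock every compound (both ionization states
#' where available) at each site, weight states by Henderson-Hasselbalch
#' fractions, optionally train FragMap weights on a designated training
#' split and redock, fit the physicochemical and consensus regressions on
#' the training split, and report metrics per model family, site and
#' state.
#'
#' @param maps_dir directory of `.dx` FragMaps.
#' @param sdf ligand SDF; records named `<id>` are neutral states and
#'   `<id>.charged` their charged counterparts.
#' @param affinity_csv CSV with columns `compound`, `exp_pic50`.
#' @param descriptor_csv optional CSV with `compound` + the five
#'   descriptors (enables the property and consensus families).
#' @param pka_csv optional CSV with `compound`, `pKa`, `kind` (enables
#'   HH-weighted scores).
#' @param sites named list of pocket centers, e.g.
#'   `list(S1 = c(0,0,0), S2 = c(5,0,0))`.
#' @param protocol a [dock_protocol] template; the pocket center and seed
#'   are overridden per site/ligand.
#' @param bml a [bml_config] to train FragMap weights, or NULL to skip.
#' @param training_ids compound ids used to fit weights and regressions;
#'   default all compounds (train = evaluation, as in training-set
#'   statistics).
#' @param pH pH for HH weighting.
#' @param seed master integer seed; every dock call derives its own.
#' @param output_dir directory for report files, or NULL to skip writing.
#' @return Object of class `run_config`.
#' @export
run_config <- function(maps_dir, sdf, affinity_csv, descriptor_csv = NULL,
                       pka_csv = NULL, sites = list(S1 = c(0, 0, 0)),
                       protocol = dock_protocol(), bml = NULL,
                       training_ids = NULL, pH = 7.4, seed = 1L,
                       output_dir = NULL) {
  for (p in c(maps_dir, sdf, affinity_csv, descriptor_csv, pka_csv))
    if (!is.null(p) && !file.exists(p)) .stopf("no such path: %s", p)
  if (is.null(names(sites)) || anyDuplicated(names(sites)))
    .stopf("sites must be uniquely named")
  structure(as.list(environment()), class = "run_config")
}

# deterministic per-dock seed from the master seed and labels
.derive_seed <- function(seed, ...) {
  h <- sum(utf8ToInt(paste(..., sep = "|")) *
             (seq_along(utf8ToInt(paste(..., sep = "|"))) %% 97 + 1))
  (as.numeric(seed) * 48271 + h) %% 2147483647
}

#' Run the full docking / reweighting / consensus pipeline
#'
#' Executes the workflow described in [run_config()] and returns (and
#' optionally writes) a report bundle: per-compound scores, the metrics
#' table with one row per model family x site x state, trained weights
#' and regression models, and a provenance record of every derived seed.
#' Runs are deterministic: the same configuration and seed give an
#' identical metrics table, byte for byte in the JSON output.
#'
#' Model families: `docking` (LGFE-derived pIC50), `ppm`
#' (five-descriptor regression) and `consensus` (descriptors + the
#' LGFE-derived prediction as a sixth regressor). States: `neutral`,
#' `charged`, `hh` (Henderson-Hasselbalch weighted); compounds without a
#' charged record contribute their neutral score to every state.
#'
#' @param config a [run_config].
#' @return List with `metrics` (data.frame), `scores` (data.frame),
#'   `weights` (trained [weight_vector] or NULL), `models` (MLR fits),
#'   `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  maps <- read_fragmap_dir(config$maps_dir)
  records <- read_sdf(config$sdf)
  rec_names <- vapply(records, function(l) l$name, character(1))
  charged_of <- grepl("\\.charged$", rec_names)
  ids <- rec_names[!charged_of]
  aff <- read.csv(config$affinity_csv, stringsAsFactors = FALSE)
  if (!all(c("compound", "exp_pic50") %in% names(aff)))
    .stopf("affinity CSV needs columns compound, exp_pic50")
  ids <- intersect(ids, aff$compound)
  if (length(ids) == 0L) .stopf("no compounds shared by SDF and affinity table")
  expv <- setNames(aff$exp_pic50, aff$compound)[ids]
  pka <- if (!is.null(config$pka_csv))
    read.csv(config$pka_csv, stringsAsFactors = FALSE) else NULL
  training_ids <- if (is.null(config$training_ids)) ids else
    intersect(config$training_ids, ids)
  if (length(training_ids) < 3L) .stopf("need at least 3 training compounds")

  neutral_of <- function(id) records[[match(id, rec_names)]]
  charged_rec <- function(id) {
    k <- match(paste0(id, ".charged"), rec_names)
    if (is.na(k)) NULL else records[[k]]
  }

  dock_all <- function(w, tag) {
    out <- list()
    failed <- character(0)
    for (site in names(config$sites)) {
      for (id in ids) {
        for (state in c("neutral", "charged")) {
          lig <- if (state == "neutral") neutral_of(id) else charged_rec(id)
          if (is.null(lig)) next
          proto <- config$protocol
          proto$pocket_center <- config$sites[[site]]
          proto$rng_seed <- .derive_seed(config$seed, tag, site, id, state)
          res <- tryCatch(
            dock(lig, maps, proto, w, site_label = site),
            error = function(e) {
              .warnf("dock failed for %s/%s/%s: %s", id, state, site,
                     conditionMessage(e))
              NULL
            })
          if (is.null(res)) failed <- union(failed, id) else
            out[[paste(site, id, state, sep = "|")]] <- res
        }
      }
    }
    if (length(failed) > length(ids) / 2)
      .stopf("more than half of the compounds failed to dock")
    list(results = out, failed = failed)
  }

  state_scores <- function(dres) {
    # per site: data.frame compound x (neutral, charged, hh) LGFE
    out <- list()
    for (site in names(config$sites)) {
      m <- matrix(NA_real_, length(ids), 3L,
                  dimnames = list(ids, c("neutral", "charged", "hh")))
      for (id in ids) {
        rn <- dres$results[[paste(site, id, "neutral", sep = "|")]]
        if (is.null(rn)) next
        m[id, "neutral"] <- rn$best_lgfe
        rc <- dres$results[[paste(site, id, "charged", sep = "|")]]
        m[id, "charged"] <- if (is.null(rc)) rn$best_lgfe else rc$best_lgfe
        krow <- if (!is.null(pka)) match(id, pka$compound) else NA
        m[id, "hh"] <- if (!is.null(rc) && !is.na(krow))
          hh_weighted_lgfe(m[id, "neutral"], m[id, "charged"],
                           pka$pKa[krow], config$pH, pka$kind[krow])
        else m[id, "neutral"]
      }
      out[[site]] <- m
    }
    out
  }

  provenance <- list(seed = config$seed,
                     package_version = as.character(utils::packageVersion("gfedock")),
                     sites = names(config$sites),
                     n_compounds = length(ids),
                     training_ids = training_ids,
                     bml = !is.null(config$bml))

  base_dock <- dock_all(NULL, "base")
  weights <- NULL
  final_dock <- base_dock
  if (!is.null(config$bml)) {
    train_site <- names(config$sites)[1]
    train_res <- lapply(training_ids, function(id)
      base_dock$results[[paste(train_site, id, "neutral", sep = "|")]])
    keep <- !vapply(train_res, is.null, logical(1))
    table <- build_gfe_table(train_res[keep], maps, unname(expv[training_ids][keep]))
    weights <- mcsa_optimize(table, config$bml)
    final_dock <- dock_all(weights, "redock")
    provenance$bml_metric <- attr(weights, "metric")
  }
  lgfes <- state_scores(final_dock)

  # regressions fitted on the training split only
  desc <- if (!is.null(config$descriptor_csv))
    read.csv(config$descriptor_csv, stringsAsFactors = FALSE) else NULL
  metrics <- list()
  scores <- list()
  add_row <- function(family, site, state, rep_) {
    metrics[[length(metrics) + 1L]] <<- data.frame(
      family = family, site = site, state = state,
      MUE = rep_$MUE, R = rep_$R, PI = rep_$PI, PC = rep_$PC, n = rep_$n)
  }
  for (site in names(config$sites)) {
    for (state in c("neutral", "charged", "hh")) {
      sc <- lgfes[[site]][, state]
      ok <- !is.na(sc)
      pred <- lgfe_to_pic50(sc[ok])
      add_row("docking", site, state, metrics_report(pred, expv[ok]))
      scores[[length(scores) + 1L]] <- data.frame(
        compound = ids[ok], site = site, state = state,
        lgfe = unname(sc[ok]), pred_pic50 = unname(pred),
        exp_pic50 = unname(expv[ok]))
      if (!is.null(desc)) {
        Xc <- build_feature_matrix(desc[match(ids[ok], desc$compound), ],
                                   pred, mode = "consensus")
        tr <- rownames(Xc) %in% training_ids
        mc_ <- fit_mlr(Xc[tr, , drop = FALSE], expv[ok][tr])
        add_row("consensus", site, state,
                metrics_report(predict(mc_, Xc), expv[ok]))
      }
    }
  }
  models <- list()
  if (!is.null(desc)) {
    Xp <- build_feature_matrix(desc[match(ids, desc$compound), ],
                               mode = "ppm_only")
    tr <- rownames(Xp) %in% training_ids
    mp <- fit_mlr(Xp[tr, , drop = FALSE], expv[tr])
    add_row("ppm", "all", "none", metrics_report(predict(mp, Xp), expv))
    models$ppm <- mp
  }
  metrics <- do.call(rbind, metrics)
  scores <- do.call(rbind, scores)

  out <- list(metrics = metrics, scores = scores, weights = weights,
              models = models, provenance = provenance)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(metrics, file.path(config$output_dir, "metrics.csv"),
              row.names = FALSE)
    jsonlite::write_json(metrics, file.path(config$output_dir, "metrics.json"),
                         dataframe = "rows", digits = NA)
    write.csv(scores, file.path(config$output_dir, "scores.csv"),
              row.names = FALSE)
    if (!is.null(weights))
      write_weights(weights, file.path(config$output_dir, "weights.yaml"))
    yaml::write_yaml(provenance, file.path(config$output_dir, "provenance.yaml"))
  }
  out
}
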