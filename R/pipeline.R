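#' Run the full hemispheric rich-club analysis
#'
#' Orchestrates every stage on a synthetic or file-based cohort:
#' fiber-number thresholding, hemisphere split, group-average network and
#' hub selection, edge classification, per-subject connectivity density /
#' strength and nodal degree, rich-club curves normalized against Maslov
#' null ensembles, asymmetry scores, group-by-hemisphere repeated-measures
#' inference with covariates, post hoc and asymmetry tests, the edge-wise
#' aberrant-connection census, and covariate-adjusted Spearman correlations
#' between peripheral degree asymmetry and clinical scores. The run is
#' deterministic given `seed` (analysis randomness) and the cohort's own
#' generator seed; the configuration hash and seed are recorded in the
#' result bundle.
#'
#' @param spec a [CohortSpec-class] used to generate the cohort when
#'   neither `cohort` nor `manifest` is supplied.
#' @param cohort an existing cohort as returned by [generateCohort()].
#' @param manifest path to a YAML manifest (see [readManifest()]); requires
#'   `phenotypes` and uses `nodes` (defaults to the packaged table).
#' @param phenotypes path to a phenotype table when loading from files.
#' @param nodes node table; defaults to the cohort's own or the packaged
#'   table.
#' @param fnThreshold fiber-number edge-adoption threshold (default 3,
#'   strict inequality).
#' @param hubFraction hub fraction (default 0.16: 7 of 45 regions).
#' @param nNull Maslov null-ensemble size per subject and hemisphere
#'   (default 1000); 0 skips rich-club normalization entirely.
#' @param nSwapPerEdge swaps per edge for each null network.
#' @param alpha significance level for post hoc gating and the census.
#' @param bonferroniM Bonferroni multiplier for nodal-degree tests
#'   (defaults to the number of regions per hemisphere).
#' @param covariates covariate column names (default age, sex, handscore).
#' @param averageMode zero-inclusive (default) or nonzero-only group
#'   averaging, see [groupAverage()].
#' @param seed master analysis seed; per-subject null seeds are derived by
#'   stable hashing of (seed, subject, hemisphere).
#' @param verbose print per-stage progress.
#' @return a result bundle (list) with elements `config`, `configHash`,
#'   `hubs`, `classification`, `metrics`, `curves`, `anovaConnectivity`,
#'   `posthoc`, `anovaDegree`, `asRecords`, `asTests`, `anovaCurves`,
#'   `census`, `spearman`, `log`.
#' @export
runPipeline <- function(spec = cohortSpec(), cohort = NULL, manifest = NULL,
                        phenotypes = NULL, nodes = NULL,
                        fnThreshold = 3L, hubFraction = 0.16, nNull = 1000L,
                        nSwapPerEdge = 10L, alpha = 0.05, bonferroniM = NULL,
                        covariates = c("age", "sex", "handscore"),
                        averageMode = "include_zeros", seed = 1L,
                        verbose = FALSE) {
  stopifnot(fnThreshold >= 0, hubFraction > 0, hubFraction < 1,
            nNull >= 0, alpha > 0, alpha < 1)
  logRows <- list()
  tic <- function() proc.time()[["elapsed"]]
  note <- function(stage, t0, msg) {
    logRows[[length(logRows) + 1]] <<- data.frame(
      stage = stage, seconds = round(tic() - t0, 3), message = msg)
    if (verbose) message(sprintf("[%s] %s", stage, msg))
  }

  ## --- input -------------------------------------------------------------
  t0 <- tic()
  if (is.null(cohort)) {
    if (!is.null(manifest)) {
      if (is.null(phenotypes)) stop("manifest input requires a phenotype table")
      man <- readManifest(manifest)
      pheno <- readPhenotypes(phenotypes)
      if (is.null(nodes)) nodes <- defaultNodeTable()
      n <- 2L * sum(nodes$hemisphere == "L")
      subjects <- lapply(seq_len(nrow(man)), function(i)
        list(subject_id = man$subject_id[i],
             fa = readMatrix(man$fa_path[i], expectedN = n,
                             hemisphereTags = nodes$hemisphere),
             fn = readFiberCounts(man$fn_path[i], expectedN = n)))
      cohort <- list(subjects = subjects, phenotypes = pheno, nodes = nodes)
      note("input", t0, sprintf("loaded %d subjects from manifest", length(subjects)))
    } else {
      cohort <- generateCohort(spec)
      note("input", t0, sprintf("simulated %d NC + %d BD subjects (seed %d)",
                                spec@nNc, spec@nBd, spec@seed))
    }
  } else note("input", t0, sprintf("using supplied cohort of %d subjects",
                                   length(cohort$subjects)))
  nodes <- cohort$nodes
  pheno <- cohort$phenotypes
  nh <- sum(nodes$hemisphere == "L")
  if (is.null(bonferroniM)) bonferroniM <- nh

  config <- list(fnThreshold = fnThreshold, hubFraction = hubFraction,
                 nNull = nNull, nSwapPerEdge = nSwapPerEdge, alpha = alpha,
                 bonferroniM = bonferroniM, covariates = covariates,
                 averageMode = averageMode, seed = as.integer(seed),
                 nSubjects = length(cohort$subjects))

  ## --- threshold + split -------------------------------------------------
  t0 <- tic()
  pairs <- lapply(cohort$subjects, function(s) {
    net <- applyFnThreshold(s$fa, s$fn, fnThreshold)
    splitHemispheres(net, nodes, subjectId = s$subject_id)
  })
  names(pairs) <- vapply(cohort$subjects, `[[`, "", "subject_id")
  note("build", t0, sprintf("thresholded (FN > %d) and split %d subjects",
                            fnThreshold, length(pairs)))

  ## --- group average + hubs + classification -----------------------------
  t0 <- tic()
  allHemis <- c(lapply(pairs, slot, "left"), lapply(pairs, slot, "right"))
  avgNet <- groupAverage(unname(allHemis), mode = averageMode)
  hubs <- selectHubs(avgNet, hubFraction)
  cls <- classifyEdges(avgNet, hubs)
  note("hubs", t0, sprintf("%d hubs / %d peripheral from pooled average",
                           length(hubIds(hubs)), length(peripheralIds(hubs))))

  ## --- per-subject measures ---------------------------------------------
  t0 <- tic()
  metricRows <- list()
  curveRows <- list()
  for (sid in names(pairs)) {
    for (hemi in c("L", "R")) {
      net <- if (hemi == "L") pairs[[sid]]@left else pairs[[sid]]@right
      cm <- connectivityMeasures(net, hubs)
      deg <- nodalDegree(net)
      metricRows[[length(metricRows) + 1]] <- data.frame(
        subject_id = sid, hemisphere = hemi,
        metric = c(cm$metric, paste0("degree_", names(deg))),
        value = c(cm$value, as.numeric(deg)))
      if (nNull > 0) {
        cur <- normalizedRichClub(net, nNull = nNull,
                                  seed = deriveSeed(seed, sid, hemi),
                                  nSwapPerEdge = nSwapPerEdge)
        cdf <- as.data.frame(cur)
        cdf$subject_id <- sid
        cdf$hemisphere <- hemi
        curveRows[[length(curveRows) + 1]] <- cdf
      }
    }
  }
  metrics <- do.call(rbind, metricRows)
  metrics <- merge(metrics, pheno, by = "subject_id", sort = FALSE)
  curves <- if (length(curveRows)) do.call(rbind, curveRows) else NULL
  note("measures", t0, sprintf("%d metric values, null ensembles of %d",
                               nrow(metrics), nNull))

  ## --- statistics --------------------------------------------------------
  t0 <- tic()
  connMetrics <- c(paste0("density_", edgeClassLevels),
                   paste0("strength_", edgeClassLevels))
  anovaConn <- do.call(rbind, lapply(connMetrics, function(mt) {
    tab <- metrics[metrics$metric == mt, ]
    res <- mixedAnova(tab, covariates)
    cbind(metric = mt, res)
  }))
  posthoc <- do.call(rbind, lapply(connMetrics, function(mt) {
    omn <- anovaConn[anovaConn$metric == mt, ]
    if (!isTRUE(any(omn$p < alpha, na.rm = TRUE))) return(NULL)
    tab <- metrics[metrics$metric == mt, ]
    cbind(metric = mt, posthocTests(tab, covariates))
  }))

  degMetrics <- grep("^degree_", unique(metrics$metric), value = TRUE)
  anovaDeg <- do.call(rbind, lapply(degMetrics, function(mt) {
    tab <- metrics[metrics$metric == mt, ]
    res <- mixedAnova(tab, covariates)
    cbind(metric = mt, res)
  }))
  anovaDeg$p_bonferroni <- bonferroni(anovaDeg$p, bonferroniM)
  anovaDeg$stars <- significanceStars(anovaDeg$p_bonferroni)

  ## asymmetry records for every metric
  asRecords <- do.call(rbind, lapply(unique(metrics$metric), function(mt) {
    tab <- metrics[metrics$metric == mt, ]
    wide <- .wideMetric(tab, covariates)
    both0 <- wide$L + wide$R == 0
    asv <- rep(NA_real_, nrow(wide))
    asv[!both0] <- asymmetryScore(wide$R[!both0], wide$L[!both0])
    out <- data.frame(subject_id = wide$subject_id, group = wide$group,
                      metric = mt, as_value = asv)
    for (cv in covariates) out[[cv]] <- wide[[cv]]
    out
  }))
  asTests <- asymmetryTests(asRecords[asRecords$metric %in% connMetrics, ],
                            covariates)
  note("stats", t0, sprintf("ANOVA on %d metrics, post hoc on %d",
                            length(connMetrics) + length(degMetrics),
                            length(unique(posthoc$metric))))

  ## --- rich-club curve group statistics ----------------------------------
  anovaCurves <- NULL
  if (!is.null(curves)) {
    t0 <- tic()
    ## restrict to levels where phi is defined for every subject x hemisphere
    nUnits <- length(pairs) * 2L
    defK <- stats::aggregate(defined ~ k, data = curves, FUN = sum)
    commonK <- defK$k[defK$defined == nUnits]
    anovaCurves <- do.call(rbind, lapply(commonK, function(kv) {
      sub <- curves[curves$k == kv, ]
      do.call(rbind, lapply(c("phi", "phi_norm"), function(what) {
        tab <- data.frame(subject_id = sub$subject_id,
                          hemisphere = sub$hemisphere, value = sub[[what]])
        tab <- merge(tab, pheno, by = "subject_id", sort = FALSE)
        cbind(k = kv, measure = what, mixedAnova(tab, covariates))
      }))
    }))
    note("richclub", t0, sprintf("group statistics at %d common degree levels",
                                 length(commonK)))
  }

  ## --- edge-wise census --------------------------------------------------
  t0 <- tic()
  ed <- edgeTable(cls)
  ids0 <- nodeIds(avgNet)
  fi <- match(ed$from, ids0); ti <- match(ed$to, ids0)
  subIdx <- cbind(fi, ti)
  leftMat <- t(vapply(pairs, function(p) edgeWeights(p@left)[subIdx],
                      numeric(nrow(ed))))
  rightMat <- t(vapply(pairs, function(p) edgeWeights(p@right)[subIdx],
                       numeric(nrow(ed))))
  census <- edgewiseCensus(leftMat, rightMat,
                           pheno$group[match(names(pairs), pheno$subject_id)],
                           cls, alpha = alpha)
  note("census", t0, sprintf("%d classified edges tested", nrow(ed)))

  ## --- clinical correlations ---------------------------------------------
  t0 <- tic()
  spearman <- NULL
  bdIds <- pheno$subject_id[pheno$group == "BD"]
  if (length(bdIds) >= 5 && any(!is.na(pheno$ymrs))) {
    periph <- peripheralIds(hubs)
    rows <- list()
    for (rg in periph) {
      rec <- asRecords[asRecords$metric == paste0("degree_", rg) &
                         asRecords$subject_id %in% bdIds, ]
      cl <- pheno[match(rec$subject_id, pheno$subject_id), ]
      for (sc in c("ymrs", "hamd")) {
        adj <- partialSpearman(rec$as_value, cl[[sc]],
                               cl[, covariates, drop = FALSE])
        raw <- partialSpearman(rec$as_value, cl[[sc]])
        rows[[length(rows) + 1]] <- data.frame(
          region = rg, score = toupper(sc),
          rho_adjusted = adj$rho, p_adjusted = adj$p,
          rho_raw = raw$rho, p_raw = raw$p, n = adj$n)
      }
    }
    spearman <- do.call(rbind, rows)
    note("clinical", t0, sprintf("Spearman on %d peripheral regions", length(periph)))
  } else note("clinical", t0, "skipped (no usable symptom scores)")

  bundle <- list(config = config, configHash = configHash(config),
                 seed = as.integer(seed), hubs = hubs, classification = cls,
                 avgNet = avgNet, metrics = metrics, curves = curves,
                 anovaConnectivity = anovaConn, posthoc = posthoc,
                 anovaDegree = anovaDeg, asRecords = asRecords,
                 asTests = asTests, anovaCurves = anovaCurves,
                 census = census, spearman = spearman,
                 log = do.call(rbind, logRows))
  class(bundle) <- "hemircResults"
  bundle
}

#' Write human-readable reports from a result bundle
#'
#' Emits tab-separated statistical tables (connectivity/degree ANOVA with
#' significance stars, post hoc tests, asymmetry tests, rich-club curve
#' statistics, the census summary, Spearman correlations) plus a markdown
#' summary. Output is a pure function of the bundle, so regenerating from a
#' saved bundle is byte-identical; every table carries the configuration
#' hash and seed in a header comment.
#'
#' @param bundle result of [runPipeline()].
#' @param dir output directory.
#' @return character vector of the files written, invisibly.
#' @export
reportPipeline <- function(bundle, dir) {
  if (is.null(bundle$anovaConnectivity)) stop("incomplete bundle: no ANOVA table")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# config %s seed %d", bundle$configHash, bundle$seed)
  files <- character(0)
  wt <- function(df, name) {
    if (is.null(df)) return()
    path <- file.path(dir, name)
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    files <<- c(files, path)
  }
  wt(bundle$anovaConnectivity, "connectivity_anova.tsv")
  wt(bundle$posthoc, "connectivity_posthoc.tsv")
  wt(bundle$anovaDegree, "degree_anova.tsv")
  wt(bundle$asTests, "asymmetry_tests.tsv")
  wt(bundle$anovaCurves, "richclub_anova.tsv")
  wt(bundle$curves, "richclub_curves.tsv")
  wt(bundle$census$edges, "census_edges.tsv")
  cens <- data.frame(test = rep(rownames(bundle$census$counts), 1),
                     bundle$census$counts,
                     check.names = FALSE)
  wt(cens, "census_counts.tsv")
  wt(bundle$spearman, "spearman.tsv")

  md <- c("# Hemispheric rich-club analysis report", "",
          sprintf("Configuration hash `%s`, analysis seed %d, %d subjects.",
                  bundle$configHash, bundle$seed, bundle$config$nSubjects),
          "",
          sprintf("Hubs (%d): %s", length(hubIds(bundle$hubs)),
                  paste(hubIds(bundle$hubs), collapse = ", ")), "",
          "## Connectivity measures (group / hemisphere / interaction)", "")
  ac <- bundle$anovaConnectivity
  md <- c(md, "| measure | class | effect | F | df | p | |",
          "|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(ac))) {
    parts <- strsplit(ac$metric[i], "_")[[1]]
    md <- c(md, sprintf("| %s | %s | %s | %.3f | %d,%d | %.4g | %s |",
                        parts[1], paste(parts[-1], collapse = "_"),
                        ac$effect[i], ac$F[i], ac$df1[i], ac$df2[i],
                        ac$p[i], ac$stars[i]))
  }
  md <- c(md, "", "## Aberrant-connection census (percent of class edges)", "",
          "| test | rich_club | feeder | local |", "|---|---|---|---|")
  pr <- bundle$census$proportions
  for (r in rownames(pr))
    md <- c(md, sprintf("| %s | %.1f | %.1f | %.1f |", r,
                        pr[r, "rich_club"], pr[r, "feeder"], pr[r, "local"]))
  mdPath <- file.path(dir, "summary.md")
  writeLines(md, mdPath)
  files <- c(files, mdPath)
  invisible(files)
}

#' @export
print.hemircResults <- function(x, ...) {
  cat(sprintf("hemirc results: %d subjects, config %s, seed %d\n",
              x$config$nSubjects, x$configHash, x$seed))
  cat(sprintf("  hubs: %s\n", paste(hubIds(x$hubs), collapse = ", ")))
  sig <- x$anovaConnectivity[x$anovaConnectivity$p < x$config$alpha, ]
  cat(sprintf("  significant connectivity effects (p < %.2f): %d of %d\n",
              x$config$alpha, nrow(sig), nrow(x$anovaConnectivity)))
  invisible(x)
}
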