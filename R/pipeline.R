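#' Pipeline configuration
#'
#' Collects every knob of an end-to-end run into one validated list:
#' input locations, catalog choice, mining thresholds, split sizes, seed,
#' stages and output directory. Referenced paths must exist at validation
#' time.
#'
#' @param input path to a compound table (CSV/SDF/SMI), or NULL to run on
#'   the synthetic generator.
#' @param fingerprints path to a precomputed wide fingerprint CSV (with a
#'   label column) — used instead of computing fingerprints from structures.
#' @param predictions named list of prediction-score CSVs for the `eval`
#'   stage (two or more enable consensus evaluation).
#' @param catalog "bundled" or a path to a SMARTS catalog CSV.
#' @param min_support,f_min,pr_min mining thresholds (see
#'   [MiningConfig()]).
#' @param split NULL, or c(n_train_pos, n_train_neg) for [splitDataset()].
#' @param synthetic_n_pos,synthetic_n_neg class sizes when `input` is NULL.
#' @param seed integer seed for every stochastic stage.
#' @param outdir output directory (created if needed).
#' @param stages subset of c("prepare", "fingerprint", "mine", "screen",
#'   "eval", "properties", "chemspace"); later stages auto-require earlier
#'   ones they depend on.
#' @return A validated config (class "nephroSAPipelineConfig").
#' @seealso [runPipeline()]
#' @export
pipelineConfig <- function(input = NULL, fingerprints = NULL,
                           predictions = NULL, catalog = "bundled",
                           min_support = 6, f_min = 0.005, pr_min = 0.75,
                           split = NULL,
                           synthetic_n_pos = 32, synthetic_n_neg = 32,
                           seed = 1, outdir = tempfile("nephroSA_run_"),
                           stages = c("prepare", "fingerprint", "mine",
                               "screen", "properties", "chemspace")) {
    all_stages <- c("prepare", "fingerprint", "mine", "screen", "eval",
        "properties", "chemspace")
    bad <- setdiff(stages, all_stages)
    if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
    for (p in c(input, fingerprints, unlist(predictions)))
        if (!is.null(p) && !file.exists(p)) stop("path not found: ", p)
    if (!identical(catalog, "bundled") && !file.exists(catalog))
        stop("catalog not found: ", catalog)
    cfg <- list(input = input, fingerprints = fingerprints,
        predictions = predictions, catalog = catalog,
        mining = list(min_support = min_support, f_min = f_min,
            pr_min = pr_min),
        split = split, synthetic_n_pos = synthetic_n_pos,
        synthetic_n_neg = synthetic_n_neg, seed = seed, outdir = outdir,
        stages = intersect(all_stages, stages))
    class(cfg) <- "nephroSAPipelineConfig"
    cfg
}

.log_msg <- function(con, ...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " | ", ...)
    message(line)
    if (!is.null(con)) writeLines(line, con)
}

.config_hash <- function(config) {
    cfg <- unclass(config)
    cfg$outdir <- NULL  # location must not change artifact identity
    .md5_of(jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null",
        digits = NA))
}

#' Run the analysis pipeline end-to-end
#'
#' Executes the requested stages in order — prepare (load, standardize,
#' deduplicate, split), fingerprint, mine, screen, eval, properties,
#' chemspace — writing one artifact per stage into the output directory
#' plus a machine-readable `summary.json`. The summary embeds the config
#' hash, the seed, the catalog hash and the mining thresholds, so a run is
#' reproducible and artifacts are attributable; with a fixed config and
#' seed the summary is byte-identical across runs. A stage failure halts
#' the run with a stage-tagged error and marks `summary.json` incomplete.
#'
#' @param config a [pipelineConfig()].
#' @return The summary list, invisibly.
#' @examples
#' \dontrun{
#' cfg <- pipelineConfig(seed = 7, outdir = tempfile())
#' res <- runPipeline(cfg)   # synthetic end-to-end run
#' res$screen$accuracy_overall
#' }
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "nephroSAPipelineConfig"))
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    logcon <- file(file.path(config$outdir, "run.log"), "a")
    on.exit(close(logcon))
    stages <- config$stages
    chash <- .config_hash(config)
    summary <- list(schema_version = "1.0", config_hash = chash,
        seed = config$seed, thresholds = config$mining,
        stages = stages, complete = FALSE)
    .write_summary <- function()
        jsonlite::write_json(summary,
            file.path(config$outdir, "summary.json"), auto_unbox = TRUE,
            digits = NA, na = "null", pretty = TRUE)
    .write_summary()
    run_stage <- function(name, expr) {
        .log_msg(logcon, "stage ", name, " start")
        tryCatch(expr, error = function(e)
            stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
    }
    .log_msg(logcon, "run start; config hash ", chash, "; seed ",
        config$seed)

    catalog <- if (identical(config$catalog, "bundled"))
        bundledAlertCatalog() else readSmartsCatalog(config$catalog)
    summary$catalog_hash <- .md5_of(paste(catalogSmarts(catalog),
        collapse = "\n"))

    set <- NULL; fpm <- NULL; labels <- NULL; alerts <- NULL

    if ("prepare" %in% stages) {
        set <- run_stage("prepare", {
            s <- if (!is.null(config$input)) loadCompounds(config$input)
                else generateSyntheticCompounds(config$synthetic_n_pos,
                    config$synthetic_n_neg, seed = config$seed)$set
            s <- deduplicateCompounds(standardizeCompounds(s))
            if (!is.null(config$split))
                s <- splitDataset(s, config$split[1], config$split[2],
                    seed = config$seed)
            writeCompounds(s, file.path(config$outdir, "compounds.csv"))
            if (nrow(rejects(s)))
                writeRejects(s, file.path(config$outdir, "rejects.csv"))
            s
        })
        d <- compoundData(set)
        summary$dataset <- list(  # class/split tallies of the prepared set
            train = list(pos = sum(d$label == 1 & d$split == "train"),
                neg = sum(d$label == 0 & d$split == "train")),
            validation = list(
                pos = sum(d$label == 1 & d$split == "validation"),
                neg = sum(d$label == 0 & d$split == "validation")),
            total = list(pos = sum(d$label == 1), neg = sum(d$label == 0),
                all = nrow(d)),
            rejects = nrow(rejects(set)))
        labels <- unname(compoundLabels(set))
    }

    if (!is.null(config$fingerprints)) {
        got <- run_stage("fingerprint", readFingerprintMatrix(
            config$fingerprints))
        fpm <- got$matrix
        if (!is.null(got$labels)) labels <- got$labels
    } else if ("fingerprint" %in% stages && !is.null(set)) {
        fpm <- run_stage("fingerprint", {
            m <- buildFingerprintMatrix(set, catalog)
            writeFingerprintMatrix(m,
                file.path(config$outdir, "fingerprints.csv"),
                labels = labels)
            m
        })
    }

    if ("mine" %in% stages && !is.null(fpm)) {
        if (is.null(labels))
            stop("[stage mine] no labels available for mining")
        alerts <- run_stage("mine", {
            a <- mineAlerts(fpm, labels, MiningConfig(
                config$mining$min_support, config$mining$f_min,
                config$mining$pr_min))
            writeAlertTable(a, file.path(config$outdir, "alerts.csv"))
            writeAlertTable(a, file.path(config$outdir, "alerts.json"),
                format = "json")
            a
        })
        summary$mining <- c(summary$thresholds,
            list(n_candidates = length(alerts),
                n_selected = length(selectedBits(alerts)),
                n_exclusive = sum(alertTable(alerts)$exclusive)))
    }

    if ("screen" %in% stages && !is.null(alerts) && !is.null(fpm)) {
        report <- run_stage("screen", {
            r <- screenSet(fpm, alerts, labels)
            writeScreenReport(r, file.path(config$outdir, "screen.json"))
            writeScreenReport(r, file.path(config$outdir, "screen.csv"))
            r
        })
        summary$screen <- as.list(screenSummary(report))
    }

    if ("eval" %in% stages && length(config$predictions)) {
        summary$eval <- run_stage("eval", {
            sets <- lapply(config$predictions, readPredictions)
            out <- lapply(sets, .eval_one)
            if (length(sets) >= 2) {
                cons <- consensusPredict(unname(sets))
                writePredictions(cons,
                    file.path(config$outdir, "consensus_scores.csv"))
                out$consensus <- .eval_one(cons)
            }
            out
        })
    }

    if ("properties" %in% stages && !is.null(set)) {
        props <- run_stage("properties", {
            p <- computeProperties(set)
            write.csv(cbind(compound_id = rownames(p), p),
                file.path(config$outdir, "properties.csv"),
                row.names = FALSE)
            p
        })
        cmp <- compareProperties(props, labels)
        write.csv(cmp, file.path(config$outdir, "property_comparison.csv"),
            row.names = FALSE)
        summary$properties <- list(
            significant = cmp$property[cmp$significant])

        if ("chemspace" %in% stages) {
            pca <- run_stage("chemspace", {
                r <- pcaChemspace(props, labels)
                write.csv(r$scores,
                    file.path(config$outdir, "chemspace_pca.csv"),
                    row.names = FALSE)
                r
            })
            summary$chemspace <- list(
                explained_pc1 = unname(pca$explained["pc1"]),
                explained_pc2 = unname(pca$explained["pc2"]))
        }
    }

    summary$complete <- TRUE
    .write_summary()
    .log_msg(logcon, "run complete")
    invisible(summary)
}

.eval_one <- function(ps) {
    labs <- unname(compoundLabels(ps))
    if (all(is.na(labs))) return(list(n = length(ps), auc = NA))
    cm <- confusion(labs, classify(ps))
    m <- metricsReport(cm, auc = rocAuc(ps))
    as.list(m)
}
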