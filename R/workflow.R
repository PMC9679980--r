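# Workflow runner: wires the modules into reproducible, manifest-writing
# commands (the same surface the command-line entry point exposes).

.WF_SCHEMA_VERSION <- "1.0"

# Required fields per command; "inputs" entries must exist on disk at
# validation time, before any output is written.
.WF_SCHEMA <- list(
  simulate = list(inputs = character(0), params = character(0)),
  features = list(inputs = "fasta", params = character(0)),
  train = list(inputs = c("fasta", "labels"), params = character(0)),
  transfer = list(inputs = c("fasta", "labels", "checkpoint"),
                  params = "mode"),
  predict = list(inputs = c("fasta", "checkpoint"), params = character(0)),
  represent = list(inputs = c("fasta", "checkpoint"), params = character(0)),
  relevance = list(inputs = c("fasta", "checkpoint"), params = character(0)),
  enrich = list(inputs = c("profiles", "annotations"), params = character(0)),
  domains = list(inputs = c("profiles", "domains"), params = character(0)),
  evaluate = list(inputs = c("pred", "truth"), params = character(0)),
  tune = list(inputs = c("fasta", "labels", "space"), params = character(0))
)

#' Package and workflow-schema version
#'
#' @return A single provenance string with the package version and the
#'   workflow configuration schema version.
#' @export
versionInfo <- function() {
  sprintf("ThermoCNN %s (workflow schema %s)",
          as.character(utils::packageVersion("ThermoCNN")),
          .WF_SCHEMA_VERSION)
}

#' Read a workflow YAML configuration
#'
#' Like [yaml::read_yaml] but resolves only the canonical `true`/`false`
#' spellings as booleans, so single-letter keys such as `n` (YAML 1.1 would
#' read them as logicals) survive as parameter names.
#'
#' @param path YAML file path.
#' @return The configuration as a named list.
#' @export
readWorkflowConfig <- function(path) {
  keep <- function(truth) function(x)
    if (toupper(x) %in% c("TRUE", "FALSE")) truth else x
  yaml::read_yaml(path, handlers = list(
    "bool#yes" = keep(TRUE), "bool#no" = keep(FALSE)))
}

.wfValidate <- function(cfg) {
  if (is.null(cfg$command) || !cfg$command %in% names(.WF_SCHEMA))
    stop("config field 'command' must be one of: ",
         paste(names(.WF_SCHEMA), collapse = ", "), call. = FALSE)
  sch <- .WF_SCHEMA[[cfg$command]]
  for (f in sch$inputs) {
    p <- cfg$inputs[[f]]
    if (is.null(p))
      stop(sprintf("command '%s' requires input '%s'", cfg$command, f),
           call. = FALSE)
    if (!file.exists(p))
      stop(sprintf("input '%s' does not exist: %s", f, p), call. = FALSE)
  }
  for (f in sch$params)
    if (is.null(cfg$params[[f]]))
      stop(sprintf("command '%s' requires parameter '%s'", cfg$command, f),
           call. = FALSE)
  if (is.null(cfg$outDir))
    stop("config field 'outDir' is required", call. = FALSE)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.wfLog <- function(cfg, fmt, ...) {
  if (!identical(cfg$logLevel, "quiet"))
    message(sprintf(paste0("[%s] ", fmt), cfg$command, ...))
}

.cfgModel <- function(p, default = modelConfig()) {
  if (is.null(p)) return(default)
  do.call(modelConfig, p)
}

.cfgTrain <- function(p, seed) {
  p <- if (is.null(p)) list() else p
  if (is.null(p$seed)) p$seed <- seed
  do.call(trainConfig, p)
}

.readProfilesForWf <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  lapply(split(df, df$id), function(d) {
    d <- d[order(d$position), ]
    new("RelevanceProfile", id = d$id[1], scores = d$score, z = d$z,
        significant = as.logical(d$significant),
        width = 0L, zThreshold = 2)
  })
}

#' Run a workflow command
#'
#' Executes one named workflow (`simulate`, `features`, `train`,
#' `transfer`, `predict`, `represent`, `relevance`, `enrich`, `domains`,
#' `evaluate` or `tune`) described by a configuration - a YAML file path or
#' an equivalent named list with fields `command`, `inputs` (named file
#' paths), `params`, `outDir`, `seed` and optional `logLevel: quiet`. The
#' configuration is validated (including existence of every referenced
#' input) before any output is written, and a `manifest.json` recording the
#' inputs, a configuration hash, the seed, the package version and a
#' checksum of every produced file is placed in `outDir`.
#'
#' @param config Path to a YAML configuration file, or a named list.
#' @return Invisibly, the manifest as a list.
#' @examples
#' out <- tempfile()
#' runWorkflow(list(command = "simulate", outDir = out, seed = 7,
#'                  params = list(n = 5), logLevel = "quiet"))
#' list.files(out)
#' @export
runWorkflow <- function(config) {
  cfg <- if (is.character(config)) readWorkflowConfig(config) else config
  cfg <- .wfValidate(cfg)
  outDir <- cfg$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  p <- cfg$params
  outputs <- character(0)
  add <- function(...) outputs <<- c(outputs, ...)

  if (cfg$command == "simulate") {
    sp <- p
    sp$seed <- cfg$seed
    sim <- generateSynthetic(do.call(syntheticSpec, sp))
    .wfLog(cfg, "generated %d records", length(sim$set))
    add(writeSyntheticData(sim, outDir))
  } else if (cfg$command == "features") {
    x <- readFastaSet(cfg$inputs$fasta)
    fr <- filterRecords(x)
    .wfLog(cfg, "%d records read, %d kept after validity filters",
           length(x), length(fr$kept))
    m <- descriptorMatrix(fr$kept)
    scaleMode <- if (is.null(p[["scale"]])) "none" else p[["scale"]]
    if (scaleMode %in% c("pooled", "all")) m <- applyScaler(m, fitScaler(m))
    f <- file.path(outDir, "features.tsv")
    add(writeDescriptorTsv(m, f))
  } else if (cfg$command %in% c("train", "transfer")) {
    x <- readProteinSet(cfg$inputs$fasta, labels = cfg$inputs$labels)
    x <- x[!is.na(labels(x))]
    model <- if (!is.null(cfg$inputs$checkpoint))
      loadThermoNet(cfg$inputs$checkpoint)
    else buildThermoNet(.cfgModel(p[["model"]]))
    mode <- if (is.null(p[["mode"]])) "from_scratch" else p[["mode"]]
    model <- setTransferMode(model, mode, seed = cfg$seed)
    fit <- trainThermoNet(model, x, .cfgTrain(p[["train"]], cfg$seed))
    .wfLog(cfg, "trained %d records, %d epochs, final train MSE %.3f",
           length(x), nrow(fit$history),
           fit$history$train_loss[nrow(fit$history)])
    ck <- file.path(outDir, "model.rds")
    saveThermoNet(fit$model, ck)
    add(ck, paste0(ck, ".json"))
    add(writeHistoryCsv(fit, file.path(outDir, "history.csv")))
  } else if (cfg$command == "predict") {
    model <- loadThermoNet(cfg$inputs$checkpoint)
    x <- readFastaSet(cfg$inputs$fasta)
    pred <- predict(model, x)
    f <- file.path(outDir, "predictions.tsv")
    add(writeLabelsTsv(data.frame(id = names(pred), label = pred), f))
  } else if (cfg$command == "represent") {
    model <- loadThermoNet(cfg$inputs$checkpoint)
    x <- readFastaSet(cfg$inputs$fasta)
    reps <- extractRepresentation(model, x)
    f <- file.path(outDir, "representations.tsv")
    utils::write.table(data.frame(id = rownames(reps), reps),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    add(f)
  } else if (cfg$command == "relevance") {
    model <- loadThermoNet(cfg$inputs$checkpoint)
    x <- readFastaSet(cfg$inputs$fasta)
    width <- if (is.null(p[["width"]])) 5L else as.integer(p[["width"]])
    profs <- lapply(seq_len(length(x)), function(i)
      occlusionProfile(model, x[i], width = width))
    .wfLog(cfg, "profiled %d sequences at width %d", length(x), width)
    add(writeProfilesTsv(profs, x, file.path(outDir, "profiles.tsv")))
  } else if (cfg$command == "enrich") {
    profs <- .readProfilesForWf(cfg$inputs$profiles)
    ann <- readSsTsv(cfg$inputs$annotations)
    annv <- stats::setNames(ann$ss, ann$id)
    alphabet <- if (is.null(p[["alphabet"]])) .DSSP8
                else strsplit(p[["alphabet"]], "")[[1]]
    alpha <- if (is.null(p[["alpha"]])) 0.05 else p[["alpha"]]
    res <- enrichCategories(profs, annv, alphabet, alpha = alpha)
    f <- file.path(outDir, "enrichment.tsv")
    utils::write.table(res, f, sep = "\t", quote = FALSE, row.names = FALSE)
    add(f)
  } else if (cfg$command == "domains") {
    profs <- .readProfilesForWf(cfg$inputs$profiles)
    dt <- readDomainsTsv(cfg$inputs$domains)
    cutoff <- if (is.null(p[["cutoff"]])) 0.30 else p[["cutoff"]]
    cov <- do.call(rbind, lapply(profs, function(pr) {
      d <- dt[dt$id == pr@id, c("name", "start", "end"), drop = FALSE]
      if (nrow(d) == 0L) return(NULL)
      cbind(id = pr@id, domainCoverage(pr, d))
    }))
    f <- file.path(outDir, "coverage.tsv")
    utils::write.table(cov, f, sep = "\t", quote = FALSE, row.names = FALSE)
    add(f)
    sel <- selectDomains(cov, cutoff = cutoff)
    f2 <- file.path(outDir, "selected_domains.txt")
    writeLines(sel, f2)
    add(f2)
  } else if (cfg$command == "evaluate") {
    pred <- readLabelsTsv(cfg$inputs$pred)
    truth <- readLabelsTsv(cfg$inputs$truth)
    mm <- merge(pred, truth, by = "id", suffixes = c(".pred", ".true"))
    met <- regressionMetrics(mm$label.true, mm$label.pred)
    add(writeMetricsJson(met, file.path(outDir, "metrics.json")))
  } else if (cfg$command == "tune") {
    space <- jsonlite::read_json(cfg$inputs$space, simplifyVector = TRUE)
    space <- lapply(space, function(v) v)
    x <- readProteinSet(cfg$inputs$fasta, labels = cfg$inputs$labels)
    x <- x[!is.na(labels(x))]
    budget <- if (is.null(p[["budget"]])) 10L else as.integer(p[["budget"]])
    objective <- function(hp) {
      mc <- .cfgModel(hp[intersect(names(hp),
        c("inputLength", "nBlocks", "filters", "kernelSize", "poolSize",
          "poolStride", "denseSizes", "dropout"))])
      tcArgs <- hp[intersect(names(hp),
        c("learningRate", "batchSize", "epochs"))]
      tcArgs$validationFraction <- 0.1
      tcArgs$seed <- cfg$seed
      fit <- trainThermoNet(buildThermoNet(mc), x, do.call(trainConfig, tcArgs))
      fit$history$val_loss[nrow(fit$history)]
    }
    res <- randomSearch(space, objective, budget = budget, seed = cfg$seed)
    f <- file.path(outDir, "search.csv")
    utils::write.table(cbind(iteration = seq_len(nrow(res)), res), f,
                       sep = ",", quote = FALSE, row.names = FALSE)
    add(f)
  }

  manifest <- list(
    command = cfg$command,
    schema_version = .WF_SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("ThermoCNN")),
    seed = cfg$seed,
    inputs = cfg$inputs,
    config_hash = .hashConfig(cfg),
    outputs = as.list(tools::md5sum(unname(outputs))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

.hashConfig <- function(cfg) {
  cfg$outDir <- NULL
  cfg$logLevel <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
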