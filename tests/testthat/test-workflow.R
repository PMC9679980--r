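test_that("version info reports the package and schema versions", {
  v <- versionInfo()
  expect_match(v, "^ThermoCNN \\d+\\.\\d+\\.\\d+")
  expect_match(v, "schema 1\\.0")
  expect_identical(v, versionInfo())
})

test_that("simulate -> train -> relevance completes end-to-end with manifests", {
  base <- withr::local_tempdir()
  simDir <- file.path(base, "sim")
  runWorkflow(list(command = "simulate", outDir = simDir, seed = 5,
                   params = list(n = 30), logLevel = "quiet"))
  man <- jsonlite::read_json(file.path(simDir, "manifest.json"))
  expect_equal(man$command, "simulate")
  expect_equal(man$seed, 5)
  for (f in names(man$outputs)) expect_true(file.exists(f))

  trainDir <- file.path(base, "train")
  runWorkflow(list(
    command = "train", outDir = trainDir, seed = 6, logLevel = "quiet",
    inputs = list(fasta = file.path(simDir, "sequences.fasta"),
                  labels = file.path(simDir, "labels.tsv")),
    params = list(
      model = list(inputLength = 128, filters = 4, poolSize = 8,
                   poolStride = 8, denseSizes = 8, dropout = 0.1),
      train = list(epochs = 2, batchSize = 16))))
  expect_true(file.exists(file.path(trainDir, "model.rds")))
  hist <- read.csv(file.path(trainDir, "history.csv"))
  expect_equal(nrow(hist), 2L)

  relDir <- file.path(base, "rel")
  runWorkflow(list(
    command = "relevance", outDir = relDir, seed = 7, logLevel = "quiet",
    inputs = list(fasta = file.path(simDir, "sequences.fasta"),
                  checkpoint = file.path(trainDir, "model.rds")),
    params = list(width = 5)))
  prof <- read.delim(file.path(relDir, "profiles.tsv"))
  expect_setequal(unique(prof$id), sprintf("SYN%05d", 1:30))

  enrDir <- file.path(base, "enr")
  runWorkflow(list(
    command = "enrich", outDir = enrDir, seed = 8, logLevel = "quiet",
    inputs = list(profiles = file.path(relDir, "profiles.tsv"),
                  annotations = file.path(simDir, "ss.tsv"))))
  enr <- read.delim(file.path(enrDir, "enrichment.tsv"))
  expect_equal(nrow(enr), 8L)
  expect_true(all(enr$p_over >= 0 & enr$p_over <= 1))
})

test_that("identical configurations reproduce identical outputs (manifests modulo timestamp)", {
  base <- withr::local_tempdir()
  cfg <- function(out) list(command = "simulate", outDir = out, seed = 42,
                            params = list(n = 12), logLevel = "quiet")
  m1 <- runWorkflow(cfg(file.path(base, "a")))
  m2 <- runWorkflow(cfg(file.path(base, "b")))
  expect_identical(m1$config_hash, m2$config_hash)
  expect_identical(unname(unlist(m1$outputs)), unname(unlist(m2$outputs)))
  expect_identical(basename(names(m1$outputs)), basename(names(m2$outputs)))
})

test_that("a missing input fails validation before any output is written", {
  out <- file.path(withr::local_tempdir(), "never")
  expect_error(runWorkflow(list(
    command = "train", outDir = out, seed = 1,
    inputs = list(fasta = "/nonexistent/x.fasta",
                  labels = "/nonexistent/y.tsv"))),
    "does not exist")
  expect_false(dir.exists(out))
  expect_error(runWorkflow(list(command = "wat", outDir = out)),
               "command")
})

test_that("evaluate joins predictions to truth and writes metrics", {
  base <- withr::local_tempdir()
  writeLabelsTsv(data.frame(id = c("a", "b", "c"), label = c(1, 2, 4)),
                 file.path(base, "pred.tsv"))
  writeLabelsTsv(data.frame(id = c("a", "b", "c"), label = c(1, 2, 3)),
                 file.path(base, "truth.tsv"))
  runWorkflow(list(command = "evaluate", outDir = file.path(base, "ev"),
                   seed = 1, logLevel = "quiet",
                   inputs = list(pred = file.path(base, "pred.tsv"),
                                 truth = file.path(base, "truth.tsv"))))
  met <- jsonlite::read_json(file.path(base, "ev", "metrics.json"))
  expect_equal(met$r2, 0.5)
  expect_equal(met$rmse, sqrt(1 / 3), tolerance = 1e-12)
})

test_that("YAML configurations drive the runner like lists do", {
  base <- withr::local_tempdir()
  yml <- file.path(base, "run.yaml")
  yaml::write_yaml(list(command = "simulate",
                        outDir = file.path(base, "out"),
                        seed = 3, params = list(n = 6),
                        logLevel = "quiet"), yml)
  man <- runWorkflow(yml)
  expect_equal(man$seed, 3)
  expect_true(file.exists(file.path(base, "out", "sequences.fasta")))
})
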