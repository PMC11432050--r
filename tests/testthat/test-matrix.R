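mkScores <- function(ids, targets, actions, scores) {
  data.frame(molecule_id = ids, target_id = targets, action = actions,
             score = scores)
}

test_that("activity matrices apply the >= cutoff at the boundary", {
  st <- mkScores(c("d1", "d2", "d3"), "T1", "agonist", c(0.69, 0.70, 0.71))
  m <- buildActivityMatrix(st, cutoff = 0.7)
  expect_identical(unname(m@mat[c("d1", "d2", "d3"), 1]), c(0L, 1L, 1L))
  # duplicated entries are an error
  dup <- rbind(st, st[1, ])
  expect_error(buildActivityMatrix(dup), "duplicated")
  # empty score table gives an empty all-zero matrix
  m0 <- buildActivityMatrix(st[0, ])
  expect_identical(sum(m0@mat), 0L)
  # direct tally on a 10 x 3 fixture
  set.seed(31)
  st2 <- mkScores(rep(sprintf("d%02d", 1:10), 3),
                  rep(c("T1", "T2", "T3"), each = 10), "agonist",
                  runif(30, -1, 1))
  m2 <- buildActivityMatrix(st2, cutoff = 0.5)
  expect_identical(sum(m2@mat), sum(st2$score >= 0.5))
})

test_that("interaction matrices are the OR over action columns", {
  st <- mkScores(rep(c("d1", "d2", "d3"), 2), "T1",
                 rep(c("agonist", "antagonist"), each = 3),
                 c(0.9, 0.1, 0.9, 0.1, 0.1, 0.9))
  act <- buildActivityMatrix(st, cutoff = 0.7)
  int <- toInteractionMatrix(act)
  # agonist=1/antagonist=0 -> 1; both 0 -> 0; both 1 -> single edge
  expect_identical(unname(int@mat[c("d1", "d2", "d3"), "T1"]),
                   c(1L, 0L, 1L))
  expect_identical(sum(int@mat), 2L)
  # idempotent on interaction input
  expect_identical(toInteractionMatrix(int)@mat, int@mat)
})

test_that("matrix comparison counts successful and new predictions", {
  ann <- data.frame(molecule_id = c("d1", "d2"), target_id = "T1",
                    action = "agonist")
  repd <- buildReportedMatrix(ann, "activity")
  cmpSelf <- compareMatrices(repd, repd)
  expect_identical(cmpSelf$n_new, 0L)
  expect_equal(cmpSelf$pct_successful, 100)

  other <- buildReportedMatrix(
    data.frame(molecule_id = "d9", target_id = "T2", action = "agonist"),
    "activity")
  cmpDisj <- compareMatrices(other, repd)
  expect_identical(cmpDisj$n_successful, 0L)

  # constructed 5-drug x 2-target case, tallied by hand
  st <- mkScores(rep(sprintf("d%d", 1:5), 2),
                 rep(c("T1", "T2"), each = 5), "agonist",
                 c(0.9, 0.8, 0.1, 0.9, 0.1, 0.1, 0.9, 0.9, 0.1, 0.1))
  pred <- buildActivityMatrix(st, cutoff = 0.7)  # d1,d2,d4@T1; d2,d3@T2
  ann2 <- data.frame(molecule_id = c("d1", "d3", "d5"),
                     target_id = c("T1", "T2", "T2"), action = "agonist")
  cmp <- compareMatrices(pred, buildReportedMatrix(ann2, "activity"))
  expect_identical(cmp$n_known, 3L)
  expect_identical(cmp$n_successful, 2L)  # d1@T1, d3@T2
  expect_identical(cmp$n_new, 3L)         # d2,d4@T1, d2@T2
  expect_error(compareMatrices(pred, toInteractionMatrix(pred)), "mode")
})

test_that("degree statistics conserve edges", {
  idm <- buildReportedMatrix(
    data.frame(molecule_id = c("a", "b", "c"),
               target_id = c("T1", "T2", "T3"), action = "agonist"),
    "interaction")
  ds <- degreeStats(idm)
  expect_true(all(ds$drugDegrees == 1))
  expect_identical(ds$meanPerDrug, 1)
  expect_identical(ds$edges, 3L)

  allOnes <- new("DrugTargetMatrix",
                 mat = matrix(1L, 2, 4,
                              dimnames = list(c("a", "b"), paste0("T", 1:4))),
                 mode = "interaction",
                 colInfo = data.frame(target = paste0("T", 1:4),
                                      action = NA_character_))
  ds2 <- degreeStats(allOnes)
  expect_true(all(ds2$drugDegrees == 4))
  expect_true(all(ds2$targetDegrees == 2))
  expect_identical(sum(ds2$drugDegrees), sum(ds2$targetDegrees))
  expect_identical(sum(ds2$drugDegrees), 8)

  # Pearson correlation against the direct formula
  x <- c(3, 1, 4, 1, 5); y <- c(2, 7, 1, 8, 2)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(degreeCorrelation(x, y), r, tolerance = 1e-12)
  expect_message(rc <- degreeCorrelation(rep(2, 5), y), "undefined")
  expect_identical(rc, NA_real_)
})

test_that("candidate selection enforces anti-target exclusion", {
  st <- mkScores(
    c("d1", "d2", "d3", "d1", "d2", "d3", "d1", "d2"),
    c(rep("CB2", 3), rep("CB1", 3), "H3", "H3"),
    c(rep("agonist", 6), "antagonist", "antagonist"),
    c(0.9, 0.9, 0.5, -0.2, 0.1, -0.5, -0.1, -0.3))
  # no anti-targets: simple cutoff selection
  expect_identical(selectCandidates(st, c("CB2", "agonist")), c("d1", "d2"))
  # d2 fails the CB1 anti-target (score 0.1 >= 0)
  anti <- data.frame(target_id = "CB1", action = "agonist")
  expect_identical(selectCandidates(st, c("CB2", "agonist"),
                                    antiTargets = anti), "d1")
  # two anti-targets, d1 passes both (-0.2, -0.1)
  anti2 <- rbind(anti, data.frame(target_id = "H3", action = "antagonist"))
  expect_identical(selectCandidates(st, c("CB2", "agonist"),
                                    antiTargets = anti2), "d1")
  # drugs missing an anti-target score are excluded with a message
  st3 <- st[-8, ]  # drop d2's H3 score
  expect_message(
    out <- selectCandidates(st3, c("CB2", "agonist"),
                            antiTargets = data.frame(target_id = "H3",
                                                     action = "antagonist")),
    "lack a score")
  expect_identical(out, "d1")
  expect_error(selectCandidates(st, c("XX", "agonist")), "unknown target")
})

test_that("random fixtures satisfy the matrix invariants", {
  for (s in 1:25) {
    fx <- generateScoreFixture(nDrugs = 30, nTargets = 4, fracKnown = 0.25,
                               seed = 100 + s)
    act <- buildActivityMatrix(fx$scores, cutoff = 0.3)
    int <- toInteractionMatrix(act)
    # single-action fixture: interaction equals activity cellwise
    expect_identical(sum(int@mat), sum(act@mat))
    ds <- degreeStats(int)
    expect_identical(sum(ds$drugDegrees), sum(ds$targetDegrees))
    expect_identical(ds$edges, sum(int@mat))
    cmp <- compareMatrices(act, buildReportedMatrix(fx$known, "activity"))
    expect_identical(cmp$n_successful + cmp$n_new, sum(act@mat))
    expect_lte(cmp$n_successful, cmp$n_known)
  }
})

test_that("matrix exports round-trip as edge lists", {
  st <- mkScores(c("d1", "d2"), "T1", "agonist", c(0.9, 0.2))
  m <- buildActivityMatrix(st, 0.7)
  el <- matrixEdgeList(m)
  expect_identical(nrow(el), 1L)
  expect_identical(el$drug, "d1")
  f <- withr::local_tempfile(fileext = ".csv")
  writeMatrixCsv(m, f)
  back <- read.csv(f, check.names = FALSE)
  expect_identical(back$drug, c("d1", "d2"))
})
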