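# Proteome scanning, single-motif homology search, clock statistics, and
# the directionality test.

test_that("decoy-only proteomes yield no propeller calls", {
  fam <- simulate_family(n_propellers = 2, motif_counts = 5,
                         age_range = c(0.2, 0.3), seed = 60)
  pr <- simulate_proteome(fam, n_decoys = 15, seed = 61)
  decoys <- Filter(function(r) grepl("^decoy", r$id), pr$proteome)
  expect_length(scan_proteome(decoys, 0.5), 0)
  expect_error(scan_proteome(list()), "non-empty")
})

test_that("planted propellers are retained according to their identity", {
  targets <- c(0.60, 0.55, 0.40)
  planted <- lapply(seq_along(targets), function(i) {
    fam <- simulate_family(n_propellers = 1, motif_counts = 5,
                           age_range = rep(age_for_identity(targets[i]), 2),
                           seed = 70 + i)
    fam$propellers[[1]]
  })
  set.seed(75)
  decoys <- lapply(1:10, function(i) {
    sequence_record(sprintf("decoy%02d", i),
                    paste(sample(AA20, 150, replace = TRUE), collapse = ""))
  })
  got <- scan_proteome(c(planted, decoys), 0.5)
  truth <- vapply(planted, function(p) true_internal_identity(p) >= 0.5,
                  logical(1))
  expect_setequal(vapply(got, `[[`, "", "parent_id"),
                  vapply(planted[truth], `[[`, "", "id"))

  # an exact tandem fusion is always retained, at identity 1
  set.seed(76)
  exact <- sequence_record("exact", strrep(
    paste(sample(AA20, 47, replace = TRUE), collapse = ""), 5))
  gotx <- scan_proteome(c(list(exact), decoys), 0.5)
  ids <- vapply(gotx, `[[`, "", "parent_id")
  expect_true("exact" %in% ids)
  ex <- gotx[[which(ids == "exact")]]
  expect_equal(ex$motif_set$avg_internal_identity, 1.0)
})

test_that("single-motif relatives are found and multi-motif subjects excluded", {
  fam <- simulate_family(n_propellers = 3, motif_counts = 5,
                         age_range = c(0.2, 0.4), seed = 80,
                         single_motif_age = age_for_identity(0.6) / 2)
  pr <- simulate_proteome(fam, n_decoys = 30, decoy_length_range = c(60, 400),
                          seed = 81)
  anns <- lapply(pr$proteome, detect_internal_repeats)
  props <- filter_by_internal_identity(anns, 0.5)
  expect_gte(length(props), 1)
  hits <- find_single_motifs(props[[1]], pr$proteome, 1e-3,
                             annotations = anns)
  expect_true("single_motif" %in% hits$subject_id)
  expect_true(all(hits$evalue < 1e-3))
  # no retained hit is itself a multi-motif propeller
  multi <- vapply(pr$proteome, function(r) {
    anns[[match(r$id, vapply(pr$proteome, `[[`, "", "id"))]]$n_motifs > 1
  }, logical(1))
  expect_false(any(hits$subject_id %in%
                     vapply(pr$proteome, `[[`, "", "id")[multi]))
})

test_that("shuffled decoys produce no sub-1e-3 hits in >= 99/100 trials", {
  fam <- simulate_family(n_propellers = 1, motif_counts = 5,
                         age_range = c(0.2, 0.2), seed = 90)
  ann <- family_annotations(fam)[[1]]
  clean <- vapply(1:100, function(s) {
    set.seed(9000 + s)
    decoys <- lapply(1:10, function(i) {
      sequence_record(sprintf("d%02d", i),
                      paste(sample(AA20, 120, replace = TRUE), collapse = ""))
    })
    nrow(find_single_motifs(ann, decoys, 1e-3)) == 0
  }, logical(1))
  expect_gte(sum(clean), 99)
})

test_that("e-values decrease monotonically with score at fixed lengths", {
  set.seed(91)
  q <- paste(sample(AA20, 47, replace = TRUE), collapse = "")
  subjects <- vapply(c(0, 5, 12, 20, 35), function(k) {
    v <- strsplit(q, "")[[1]]
    if (k > 0) {
      pos <- seq_len(k)
      v[pos] <- vapply(v[pos], function(r) setdiff(AA20, r)[1], "")
    }
    paste(v, collapse = "")
  }, "")
  als <- lapply(subjects, local_alignment, query = q)
  sc <- vapply(als, `[[`, numeric(1), "score")
  ev <- vapply(als, `[[`, numeric(1), "evalue")
  bs <- vapply(als, `[[`, numeric(1), "bitscore")
  ord <- order(sc)
  expect_true(all(diff(ev[ord]) <= 0))
  expect_true(all(diff(bs[ord]) >= 0))
})

test_that("clock points carry avg <= max with equality for identical repeats", {
  fam <- simulate_family(seed = 95)
  ck <- clock_statistics(family_annotations(fam), fam$single_motif)
  expect_true(all(ck$points$id_to_single_max >=
                    ck$points$id_to_single_avg - 1e-12))

  set.seed(96)
  motif <- paste(sample(AA20, 47, replace = TRUE), collapse = "")
  rec <- sequence_record("ident", strrep(motif, 5))
  rec$boundaries <- cbind(47 * (0:4), 47 * (1:5))
  rec$n_motifs <- 5L
  fam_ident <- list(propellers = list(rec))
  ann <- family_annotations(fam_ident)
  pts <- clock_statistics(ann, sequence_record("s", motif))$points
  expect_equal(pts$id_to_single_avg, pts$id_to_single_max)
})

test_that("clock statistics honor the stated contracts", {
  fam <- simulate_family(seed = 97)
  anns <- family_annotations(fam)
  # two propellers: points but no correlation
  ck2 <- clock_statistics(anns[1:2], fam$single_motif)
  expect_equal(nrow(ck2$points), 2)
  expect_null(ck2$correlation)
  # order invariance
  ckA <- clock_statistics(anns, fam$single_motif)
  ckB <- clock_statistics(rev(anns), fam$single_motif)
  expect_equal(ckA$correlation$r, ckB$correlation$r, tolerance = 1e-12)
  # zero variance in an axis is an error
  set.seed(98)
  motif <- paste(sample(AA20, 47, replace = TRUE), collapse = "")
  recs <- lapply(1:3, function(i) {
    r <- sequence_record(paste0("p", i), strrep(motif, 5))
    r$boundaries <- cbind(47 * (0:4), 47 * (1:5)); r$n_motifs <- 5L; r
  })
  expect_error(
    clock_statistics(family_annotations(list(propellers = recs)),
                     sequence_record("s", motif)),
    "zero variance")
})

test_that("clock correlation strengthens with the spread of propeller ages", {
  spreads <- list(c(0.1, 0.25), c(0.1, 0.7), c(0.1, 1.5))
  mean_r <- vapply(seq_along(spreads), function(i) {
    mean(vapply(1:8, function(s) {
      fam <- simulate_family(age_range = spreads[[i]], seed = 500 + s)
      clock_statistics(family_annotations(fam),
                       fam$single_motif)$correlation$r
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0))
})

test_that("directionality separates motif-first from co-option scenarios", {
  famA <- simulate_family(seed = 130, scenario = "A")
  ckA <- clock_statistics(family_annotations(famA), famA$single_motif)
  dA <- directionality_test(ckA$points, seed = 1)
  expect_equal(dA$verdict, "motif-origin consistent")

  famB <- simulate_family(seed = 131, scenario = "B")
  ckB <- clock_statistics(family_annotations(famB), famB$single_motif)
  dB <- directionality_test(ckB$points, seed = 1)
  expect_equal(dB$verdict, "co-option suspected")
  # the copied-from propeller is the flagged one
  expect_true(dB$table$flagged[dB$table$propeller_id == "prop01"])

  # exactly equidistant repeats: observed gap 0, consistent
  pts <- data.frame(propeller_id = c("p1", "p2", "p3"), n_motifs = 5L,
                    internal_identity = c(90, 75, 60),
                    id_to_single_avg = c(85, 70, 55),
                    id_to_single_max = c(85, 70, 55))
  attr(pts, "per_motif_identity") <- list(p1 = rep(85, 5), p2 = rep(70, 5),
                                          p3 = rep(55, 5))
  d0 <- directionality_test(pts, seed = 2)
  expect_equal(d0$table$observed_gap, rep(0, 3))
  expect_equal(d0$verdict, "motif-origin consistent")
})
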