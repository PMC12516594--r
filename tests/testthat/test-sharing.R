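## 6 doculects, 2 per family, with a deliberately mixed sharing structure
sharing_fixture <- function() {
  s <- rbind(
    r01 = c(1L, 1L, 0L, 0L, 0L, 0L),   # KXA only -> NONE
    r02 = c(1L, 0L, 1L, 0L, 0L, 0L),   # KXA+TUU
    r03 = c(0L, 1L, 0L, 1L, 1L, 0L),   # KXA+TUU+KK
    r04 = c(0L, 0L, 1L, 0L, 1L, 1L),   # TUU+KK
    r05 = c(1L, 0L, 0L, 0L, 0L, 1L),   # KXA+KK
    r06 = c(NA, 0L, 1L, 1L, 1L, 0L),   # '?' in KXA: TUU+KK only
    r07 = c(0L, 0L, 0L, 0L, 1L, 1L))   # KK only -> NONE
  colnames(s) <- c("k1", "k2", "t1", "t2", "h1", "h2")
  toy_matrix(s, families = c("KXA", "KXA", "TUU", "TUU", "KHOE_KWADI",
                             "KHOE_KWADI"),
             origins = c("KXA", "UNIDENTIFIED", "KXA", "KHOE_KWADI",
                         "KHOE_KWADI", "TUU", "KHOE_KWADI"),
             clusters = c("ck", "ck", "ct1", "ct2", "ch", "ch"))
}

test_that("detect_shared classifies attestation patterns from present states only", {
  m <- sharing_fixture()
  rec <- detect_shared(m)
  pat <- setNames(rec$pattern, rec$root_id)
  expect_equal(pat[["r01"]], "NONE")
  expect_equal(pat[["r02"]], "KXA_TUU")
  expect_equal(pat[["r03"]], "KXA_TUU_KK")
  expect_equal(pat[["r04"]], "TUU_KK")
  expect_equal(pat[["r05"]], "KXA_KK")
  expect_equal(pat[["r06"]], "TUU_KK")   # missing is not attestation
  expect_equal(pat[["r07"]], "NONE")
  expect_true(all((rec$pattern == "NONE") == (rec$n_families < 2)))
  expect_setequal(rec$doculects[[match("r03", rec$root_id)]],
                  c("k2", "t2", "h1"))
})

test_that("detect_shared ignores doculect order and all-absent doculects", {
  m <- sharing_fixture()
  rec <- detect_shared(m)
  perm <- rev(colnames(m$state))
  m2 <- toy_matrix(m$state[, perm], families = doculect_families(m)[perm],
                   origins = m$roots$origin)
  rec2 <- detect_shared(m2)
  expect_equal(rec2$pattern, rec$pattern)
  s3 <- cbind(m$state, extra = 0L)
  m3 <- toy_matrix(s3, families = c(doculect_families(m), "TUU"),
                   origins = m$roots$origin)
  expect_equal(detect_shared(m3)$pattern, rec$pattern)
})

test_that("pattern and origin proportions count shared roots and sum to one", {
  m <- sharing_fixture()
  rec <- detect_shared(m)
  pp <- pattern_proportions(rec)
  expect_equal(sum(pp), 1)
  expect_equal(as.numeric(pp[c("KXA_TUU_KK", "KXA_KK", "TUU_KK", "KXA_TUU")]),
               c(1, 1, 2, 1) / 5)
  op <- origin_proportions(rec)
  expect_equal(sum(op), 1)
  expect_equal(as.numeric(op[c("KXA", "TUU", "KHOE_KWADI", "UNIDENTIFIED")]),
               c(1, 1, 2, 1) / 5)
  # degenerate: single pattern
  one <- rec[rec$pattern %in% c("NONE", "KXA_TUU"), ]
  expect_equal(as.numeric(pattern_proportions(one)["KXA_TUU"]), 1)
  expect_warning(pattern_proportions(rec[rec$pattern == "NONE", ]),
                 "no shared roots")
})

test_that("origin proportions refuse unannotated shared roots", {
  m <- sharing_fixture()
  m$roots$origin[m$roots$id == "r03"] <- "UNANNOTATED"
  expect_error(origin_proportions(detect_shared(m)), "r03")
})

test_that("doculect fractions partition the attested roots", {
  m <- sharing_fixture()
  rec <- detect_shared(m)
  # brute-force check for h1 (family KHOE_KWADI):
  # present roots r03, r04, r06, r07; r03 (origin KXA) and r06 (TUU) are
  # loans, r04 (KK) is donated, r07 is family-private
  fr <- doculect_fractions(m, rec, "h1")
  expect_equal(fr$n_present, 4)
  expect_equal(fr$borrowed, 2 / 4)
  expect_equal(fr$donated, 1 / 4)
  expect_equal(fr$unresolved_shared, 0)
  expect_equal(fr$unshared, 1 / 4)
  expect_equal(unname(fr$borrowed_by_donor[c("KXA", "TUU")]), c(1, 1) / 4)
  # t1 (TUU): r02 unresolved-shared, r04 borrowed from KK, r06 donated
  ft <- doculect_fractions(m, rec, "t1")
  expect_equal(ft$n_present, 3)
  expect_equal(ft$unresolved_shared, 1 / 3)
  expect_equal(ft$borrowed, 1 / 3)
  expect_equal(ft$donated, 1 / 3)
  expect_equal(fr$borrowed + fr$donated + fr$unresolved_shared + fr$unshared, 1)
  expect_error(doculect_fractions(m, rec, "nope"), "unknown doculect")
})

test_that("fraction partition sums to one on random annotated matrices", {
  set.seed(77)
  for (rep in 1:20) {
    s <- random_state_matrix(30, 6)
    m <- toy_matrix(s, families = c("KXA", "KXA", "TUU", "TUU",
                                    "KHOE_KWADI", "KHOE_KWADI"),
                    origins = sample(c(SAK_FAMILIES, "UNIDENTIFIED"), 30,
                                     replace = TRUE))
    rec <- detect_shared(m)
    for (d in colnames(s)) {
      fr <- doculect_fractions(m, rec, d)
      expect_equal(fr$borrowed + fr$donated + fr$unresolved_shared +
                     fr$unshared, 1, tolerance = 1e-12)
      expect_equal(fr$shared + fr$unshared, 1, tolerance = 1e-12)
    }
  }
})

test_that("doculect with no attested roots is an error", {
  s <- rbind(r1 = c(1L, 0L), r2 = c(1L, NA))
  m <- toy_matrix(s, families = c("KXA", "TUU"),
                  origins = c("KXA", "KXA"))
  expect_error(doculect_fractions(m, detect_shared(m), "d02"),
               "no attested roots")
})

test_that("cluster profiles average member doculects, unweighted by default", {
  m <- sharing_fixture()
  rec <- detect_shared(m)
  # singleton cluster equals its doculect
  p1 <- cluster_profile(m, rec, "ct1")
  f1 <- doculect_fractions(m, rec, "t1")
  expect_equal(p1$borrowed, f1$borrowed)
  expect_equal(p1$shared, f1$shared)
  # two-member cluster is the plain mean
  ph <- cluster_profile(m, rec, "ch")
  fh1 <- doculect_fractions(m, rec, "h1")
  fh2 <- doculect_fractions(m, rec, "h2")
  expect_equal(ph$borrowed, (fh1$borrowed + fh2$borrowed) / 2)
  expect_equal(ph$max_member_shared, max(fh1$shared, fh2$shared))
  # weighted averaging weights by attested-root counts
  phw <- cluster_profile(m, rec, "ch", weighted = TRUE)
  wts <- c(fh1$n_present, fh2$n_present)
  expect_equal(phw$borrowed,
               sum(c(fh1$borrowed, fh2$borrowed) * wts) / sum(wts))
  expect_error(cluster_profile(m, rec, "nope"), "no members")
})

test_that("resolution decomposition groups loanwords by donor and proto-level", {
  m <- example_matrix()
  rec <- detect_shared(filter_roots(m))
  rd <- resolution_decomposition(rec)
  kk <- rd[rd$donor == "KHOE_KWADI", ]
  expect_setequal(kk$level, c("Proto-Khoekhoe", "Proto-Khoe"))
  expect_equal(sum(kk$fraction), 1)
  expect_equal(rd$count[rd$donor == "TUU" & rd$level == "Proto-Taa"], 1)
  # recipient scoping: KK loans received by TUU = r01 only
  rd_tuu <- resolution_decomposition(rec, recipient_families = "TUU")
  expect_equal(rd_tuu$count[rd_tuu$donor == "KHOE_KWADI"], 1)
  # inconsistent proto-level inventory triggers an integrity error
  inv <- list(KHOE_KWADI = "Proto-Khoe", TUU = "Proto-Taa", KXA = "Proto-Kx'a")
  expect_error(resolution_decomposition(rec, level_inventory = inv),
               "inconsistent")
})

test_that("unresolved roots classify as areal, distant or outlier by geography", {
  # six doculects on a line, 3 degrees (~310 km) apart; radius 320 km makes
  # immediate neighbours adjacent and nothing else
  s <- rbind(
    near = c(0L, 1L, 1L, 0L, 0L, 0L),    # adjacent cross-family pair -> AREAL
    far  = c(1L, 0L, 0L, 0L, 0L, 1L),    # opposite ends -> DISTANT
    scat = c(1L, 0L, 0L, 1L, 0L, 1L))    # 3 isolated attestations -> OUTLIER
  colnames(s) <- paste0("d", 1:6)
  m <- toy_matrix(s, families = c("KXA", "KXA", "TUU", "TUU", "KHOE_KWADI",
                                  "KHOE_KWADI"),
                  origins = rep("UNIDENTIFIED", 3),
                  lat = rep(-22, 6), lon = seq(16, 31, by = 3))
  rec <- detect_shared(m)
  cls <- classify_unresolved(rec, m$doculects, radius_km = 320,
                             patterns = c("KXA_TUU", "KXA_TUU_KK",
                                          "KXA_KK", "TUU_KK"))
  got <- setNames(cls$category, cls$root_id)
  expect_equal(got[["near"]], "AREAL")
  expect_equal(got[["far"]], "DISTANT")
  expect_equal(got[["scat"]], "OUTLIER")
  # proto-level reconstruction in two families forces DISTANT
  cls2 <- classify_unresolved(rec, m$doculects, radius_km = 320,
                              proto_families = c(near = 2L),
                              patterns = "KXA_TUU")
  expect_equal(cls2$category[cls2$root_id == "near"], "DISTANT")
  # no coordinates and no explicit adjacency -> config error
  m2 <- toy_matrix(s, families = c("KXA", "KXA", "TUU", "TUU", "KHOE_KWADI",
                                   "KHOE_KWADI"),
                   origins = rep("UNIDENTIFIED", 3))
  expect_error(classify_unresolved(detect_shared(m2), m2$doculects,
                                   patterns = "KXA_TUU"),
               "coordinates missing")
  # explicit adjacency overrides the radius entirely
  adj <- doculect_adjacency(m2$doculects, pairs = cbind("d1", "d6"))
  cls3 <- classify_unresolved(rec, m2$doculects, adjacency = adj,
                              patterns = c("KXA_TUU", "KXA_TUU_KK",
                                           "KXA_KK", "TUU_KK"))
  expect_equal(cls3$category[cls3$root_id == "far"], "AREAL")
})

test_that("report writer emits consistent tables and a JSON summary", {
  m <- filter_roots(example_matrix())
  rec <- detect_shared(m)
  dir <- withr::local_tempdir()
  files <- write_sharing_report(m, rec, dir)
  expect_true(all(file.exists(files)))
  tab <- read.delim(file.path(dir, "sharing_records.tsv"))
  expect_equal(nrow(tab), nrow(m$state))
  pp <- read.delim(file.path(dir, "pattern_proportions.tsv"))
  expect_equal(sum(pp$fraction), 1)
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$n_roots, nrow(m$state))
  expect_equal(js$n_shared, sum(rec$pattern != "NONE"))
})
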