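write_evidence <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  p <- file.path(dir, "evidence.tsv")
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

test_that("evidence loader validates names and fills unstated cells with NA", {
  ev <- data.frame(root_id = "r1", family = c("KXA", "TUU"),
                   criterion = "PHONOLOGY",
                   value = c("SUPPORTS", "NEUTRAL"))
  full <- load_evidence(write_evidence(ev))
  expect_equal(nrow(full), 2 * 8)    # 2 families x 8 criteria
  expect_setequal(unique(full$value[full$criterion != "PHONOLOGY"]), "NA")
  expect_error(load_evidence(write_evidence(transform(ev, criterion = "VIBES"))),
               "unknown criterion")
  expect_error(load_evidence(write_evidence(transform(ev, value = "MAYBE"))),
               "unknown criterion value")
  expect_error(load_evidence(write_evidence(rbind(ev, ev[1, ]))),
               "duplicate evidence")
})

test_that("origin decisions cover the trivial evidence situations", {
  neutral <- expand.grid(root_id = "r1", family = c("KXA", "TUU"),
                         criterion = c(borrownet:::PRIMARY_CRITERIA,
                                       borrownet:::SECONDARY_CRITERIA),
                         value = "NEUTRAL", stringsAsFactors = FALSE)
  d <- decide_origin(neutral)
  expect_equal(d$origin, "UNIDENTIFIED")
  expect_true(length(d$trace) > 0)
  sup <- neutral
  sup$value[sup$family == "KXA" & sup$criterion == "PHONOLOGY"] <- "SUPPORTS"
  expect_equal(decide_origin(sup)$origin, "KXA")
  both <- sup
  both$value[both$family == "TUU" &
               both$criterion == "RECONSTRUCTABILITY"] <- "SUPPORTS"
  expect_equal(decide_origin(both)$origin, "UNIDENTIFIED")
  expect_error(decide_origin(neutral[neutral$family == "KXA", ]),
               "at least 2 candidate families")
})

test_that("the full 2-family truth table matches an independent rule evaluator", {
  policy <- origin_policy(primary = c("P1", "P2"), secondary = c("S1", "S2"))
  vals <- c("SUPPORTS", "CONTRADICTS", "NEUTRAL", "NA")
  grid <- expand.grid(a_P1 = vals, a_P2 = vals, b_P1 = vals, b_P2 = vals,
                      a_S1 = vals, b_S1 = vals, stringsAsFactors = FALSE)
  set.seed(8)
  grid <- grid[sample(nrow(grid), 600), ]   # 600 random rows of the table
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    values <- list(
      KXA = c(P1 = g$a_P1, P2 = g$a_P2, S1 = g$a_S1, S2 = "NEUTRAL"),
      TUU = c(P1 = g$b_P1, P2 = g$b_P2, S1 = g$b_S1, S2 = "NEUTRAL"))
    want <- origin_rule_oracle(values)
    got <- decide_origin(evidence_from_values(values), policy)$origin
    expect_identical(got, want)
  }
  # plus the exhaustive primary-only table (256 combinations)
  gridp <- expand.grid(a_P1 = vals, a_P2 = vals, b_P1 = vals, b_P2 = vals,
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(gridp))) {
    g <- gridp[i, ]
    values <- list(
      KXA = c(P1 = g$a_P1, P2 = g$a_P2, S1 = "NA", S2 = "NA"),
      TUU = c(P1 = g$b_P1, P2 = g$b_P2, S1 = "NA", S2 = "NA"))
    expect_identical(decide_origin(evidence_from_values(values), policy)$origin,
                     origin_rule_oracle(values))
  }
})

test_that("decisions are deterministic and monotone in supporting evidence", {
  policy <- origin_policy(primary = c("P1", "P2"), secondary = c("S1", "S2"))
  vals <- c("SUPPORTS", "CONTRADICTS", "NEUTRAL", "NA")
  set.seed(9)
  for (rep in 1:150) {
    values <- list(
      KXA = setNames(sample(vals, 4, TRUE), c("P1", "P2", "S1", "S2")),
      TUU = setNames(sample(vals, 4, TRUE), c("P1", "P2", "S1", "S2")))
    ev <- evidence_from_values(values)
    d1 <- decide_origin(ev, policy)$origin
    expect_identical(decide_origin(ev, policy)$origin, d1)   # determinism
    if (d1 %in% names(values)) {
      # upgrading a non-SUPPORTS primary cell of the winner keeps it winning
      v2 <- values
      up <- which(v2[[d1]][c("P1", "P2")] != "SUPPORTS")
      if (length(up)) {
        v2[[d1]][c("P1", "P2")[up[1]]] <- "SUPPORTS"
        expect_identical(decide_origin(evidence_from_values(v2), policy)$origin,
                         d1)
      }
      # a new primary SUPPORTS for the rival never strengthens the winner
      rival <- setdiff(names(values), d1)
      v3 <- values
      dn <- which(v3[[rival]][c("P1", "P2")] != "SUPPORTS")
      if (length(dn)) {
        v3[[rival]][c("P1", "P2")[dn[1]]] <- "SUPPORTS"
        expect_true(decide_origin(evidence_from_values(v3), policy)$origin
                    %in% c(d1, "UNIDENTIFIED", rival))
      }
    }
  }
})

test_that("symmetric primary evidence always yields UNIDENTIFIED", {
  policy <- origin_policy(primary = c("P1", "P2"), secondary = c("S1", "S2"))
  vals <- c("SUPPORTS", "CONTRADICTS", "NEUTRAL", "NA")
  for (v1 in vals) for (v2 in vals) {
    values <- list(KXA = c(P1 = v1, P2 = v2, S1 = "NEUTRAL", S2 = "NEUTRAL"),
                   TUU = c(P1 = v1, P2 = v2, S1 = "NEUTRAL", S2 = "NEUTRAL"))
    expect_identical(decide_origin(evidence_from_values(values), policy)$origin,
                     "UNIDENTIFIED")
  }
})

test_that("batch decisions count one per root and report agreement", {
  ev <- rbind(
    data.frame(root_id = "r1", family = c("KXA", "TUU"),
               criterion = "PHONOLOGY", value = c("SUPPORTS", "NEUTRAL")),
    data.frame(root_id = "r2", family = c("KXA", "TUU"),
               criterion = "RECONSTRUCTABILITY",
               value = c("NEUTRAL", "SUPPORTS")),
    data.frame(root_id = "r3", family = c("KXA", "TUU"),
               criterion = "GEOGRAPHY", value = c("SUPPORTS", "NEUTRAL")))
  full <- load_evidence(write_evidence(ev))
  gold <- c(r1 = "KXA", r2 = "TUU", r3 = "KXA")
  dec <- batch_decide(full, gold = gold)
  expect_equal(nrow(dec), 3)
  expect_equal(setNames(dec$origin, dec$root_id),
               c(r1 = "KXA", r2 = "TUU", r3 = "UNIDENTIFIED"))
  ag <- attr(dec, "agreement")
  expect_equal(ag$n, 3)
  expect_equal(ag$fraction, 2 / 3)
  expect_equal(ag$disagreements, "r3")
})

test_that("policies load from YAML and reject unknown keys", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "policy.yaml")
  writeLines(c("primary:", "  - P1", "  - P2", "secondary:", "  - S1",
               "min_primary_score: 2"), p)
  pol <- read_origin_policy(p)
  expect_equal(pol$primary, c("P1", "P2"))
  expect_equal(pol$min_primary_score, 2)
  # a single SUPPORTS no longer suffices under min_primary_score = 2
  values <- list(KXA = c(P1 = "SUPPORTS", P2 = "NEUTRAL", S1 = "NEUTRAL"),
                 TUU = c(P1 = "NEUTRAL", P2 = "NEUTRAL", S1 = "NEUTRAL"))
  expect_equal(decide_origin(evidence_from_values(values), pol)$origin,
               "UNIDENTIFIED")
  writeLines("tertiary: [X]", p)
  expect_error(read_origin_policy(p), "unknown policy key")
})
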