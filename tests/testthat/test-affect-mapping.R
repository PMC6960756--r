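test_that("keyword mapping is nearest-neighbour with table-order ties", {
  tab <- emotion_keywords()
  # idempotence: a keyword's own coordinates map to that keyword
  for (i in seq_len(nrow(tab))) {
    hit <- map_to_keyword(c(tab$valence[i], tab$arousal[i]), tab)
    expect_equal(hit$keyword, tab$keyword[i])
    expect_equal(hit$distance, 0)
  }

  # distance-enumeration oracle for an off-grid point
  pt <- c(0.9, 0.9)
  d2 <- (tab$valence - pt[1])^2 + (tab$arousal - pt[2])^2
  expect_equal(map_to_keyword(pt, tab)$keyword, tab$keyword[which.min(d2)])
  expect_true(map_to_keyword(pt, tab)$keyword %in%
                c("excited", "happy", "pleased", "peaceful", "calm"))
  expect_true(map_to_keyword(pt, tab)$keyword %in%
                c("excited", "happy", "fear", "suspense"))

  # deterministic tie-break: first row wins at equal distance
  tie_tab <- data.frame(keyword = c("a", "b"),
                        valence = c(1, -1), arousal = c(0, 0))
  expect_equal(map_to_keyword(c(0, 0), tie_tab)$keyword, "a")

  expect_error(map_to_keyword(c(0, 0), tie_tab[0, ]),
               class = "invalid_argument")
})

test_that("origin reflection flips quadrants under a sign-symmetric table", {
  sym <- data.frame(
    keyword = c("pp", "pn", "np", "nn"),
    valence = c(0.6, 0.6, -0.6, -0.6),
    arousal = c(0.6, -0.6, 0.6, -0.6)
  )
  set.seed(5)
  for (i in 1:25) {
    pt <- runif(2, 0.05, 1)  # strictly positive quadrant
    hit <- map_to_keyword(pt, sym)$keyword
    mirrored <- map_to_keyword(-pt, sym)$keyword
    expect_equal(hit, "pp")
    expect_equal(mirrored, "nn")
  }
})

test_that("responses assemble one row per subject and keyword", {
  kt <- emotion_keywords()
  mk_scores <- function(sid, group) {
    data.frame(subject_id = sid, group = group,
               medium = rep(c("photograph", "artwork"), each = 9),
               keyword = rep(kt$keyword, 2),
               valence = runif(18, -1, 1), arousal = runif(18, -1, 1))
  }
  set.seed(2)
  scores <- do.call(rbind, c(
    lapply(sprintf("ph%02d", 1:20), mk_scores, group = "photograph"),
    lapply(sprintf("aw%02d", 1:20), mk_scores, group = "artwork")
  ))
  resp <- assemble_responses(scores)
  expect_equal(length(unique(resp$subject_id)), 40)
  expect_equal(nrow(resp), 40 * 9)
  # only own-medium clips are kept
  one <- scores[scores$subject_id == "ph01" &
                  scores$medium == "photograph" &
                  scores$keyword == "calm", ]
  expect_equal(resp$valence[resp$subject_id == "ph01" &
                              resp$keyword == "calm"], one$valence)

  # duplicates for a keyword are averaged with a warning
  dup <- mk_scores("dd01", "artwork")
  extra <- dup[dup$medium == "artwork" & dup$keyword == "sad", ]
  extra$valence <- extra$valence + 0.2
  dup2 <- rbind(dup, extra)
  expect_warning(r2 <- assemble_responses(dup2), "averaging")
  expect_equal(r2$valence[r2$keyword == "sad"],
               mean(dup2$valence[dup2$medium == "artwork" &
                                   dup2$keyword == "sad"]))

  # a subject missing a keyword is an error naming both
  miss <- mk_scores("mm01", "photograph")
  miss <- miss[!(miss$medium == "photograph" & miss$keyword == "fear"), ]
  err <- tryCatch(assemble_responses(miss), condition = identity)
  expect_s3_class(err, "incomplete_subject")
  expect_match(conditionMessage(err), "mm01")
  expect_match(conditionMessage(err), "fear")

  expect_equal(nrow(assemble_responses(scores[0, ])), 0)
})
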