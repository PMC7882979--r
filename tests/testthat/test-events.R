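test_that("the 15-min rule chains transitively within a camera", {
  # gaps of 10 and 14 min chain into one event despite a 24-min span
  ev <- group_events(videos_at("cam1", c(0, 10, 24)))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_videos, 3)
  expect_equal(ev$video_ids, "cam1_v1;cam1_v2;cam1_v3")

  # a 16-min gap starts a new event
  ev2 <- group_events(videos_at("cam1", c(0, 16)))
  expect_equal(nrow(ev2), 2)

  # the boundary is inclusive: exactly 15 min still merges
  ev3 <- group_events(videos_at("cam1", c(0, 15)))
  expect_equal(nrow(ev3), 1)

  # different cameras never merge, even simultaneously
  ev4 <- group_events(rbind(videos_at("cam1", 0), videos_at("cam2", 0)))
  expect_equal(nrow(ev4), 2)

  bad <- videos_at("cam1", 0)
  bad$start_timestamp <- NA
  expect_error(group_events(bad), "missing start_timestamp")
})

test_that("regrouping an event's own member videos reproduces it", {
  dat <- simulate_community(sim_config(n_events = 40, seed = 12))
  ev <- group_events(dat$videos)
  for (i in seq_len(nrow(ev))) {
    vids <- strsplit(ev$video_ids[i], ";")[[1]]
    sub <- dat$videos[dat$videos$video_id %in% vids, ]
    again <- group_events(sub)
    expect_equal(nrow(again), 1)
    expect_equal(again$video_ids, ev$video_ids[i])
  }
})

test_that("gambit parties are the union of identified individuals per event", {
  dat <- simulate_community(sim_config(n_events = 30, seed = 9))
  ev <- group_events(dat$videos)
  parties <- gambit_party(ev, dat$detections, "expert")
  d <- dat$detections[dat$detections$channel == "expert" &
                        !is.na(dat$detections$individual_id), ]
  for (i in seq_len(nrow(ev))) {
    vids <- strsplit(ev$video_ids[i], ";")[[1]]
    expect_setequal(parties[[ev$event_id[i]]],
                    unique(d$individual_id[d$video_id %in% vids]))
  }
  # all-unidentified events yield the empty party
  none <- gambit_party(ev[1, ], dat$detections[0, ], "expert")
  expect_length(none[[1]], 0)
})

test_that("the shared roster is weaned individuals identified in both channels", {
  det <- data.frame(
    video_id = "v1", camera_id = "c1",
    start_timestamp = "2020-01-01T00:00:00Z",
    channel = c("expert", "expert", "expert", "citizen", "citizen"),
    clip_positions = "1",
    individual_id = c("A", "B", "C", "caruso", "C"),
    age_sex_class = "adult_female",
    weaned = c(1L, 1L, 0L, 1L, 0L),
    token = paste0("t", 1:5), stringsAsFactors = FALSE
  )
  idmap <- data.frame(citizen_id = c("caruso", "C"),
                      expert_id = c("A", "C"), stringsAsFactors = FALSE)
  # B only identified by experts; C identified by both but unweaned
  expect_equal(select_shared_roster(det, id_map = idmap), "A")
  expect_error(select_shared_roster(det, id_map = idmap[1, ]),
               "unmapped citizen ID")
  # synthetic-data path: full overlap, identity mapping
  dat <- simulate_community(sim_config(n_events = 200, seed = 3))
  roster <- select_shared_roster(dat$detections)
  expect_setequal(roster, names(which(dat$truth$weaned)))
})

test_that("the simple ratio index matches its closed form", {
  # x = 2, yA = 1, yB = 1 -> 2/4
  parties <- list(c("A", "B"), c("A", "B"), "A", "B", "C")
  expect_equal(simple_ratio_index(parties, c("A", "B")), 0.5)
  # never co-detected
  expect_equal(simple_ratio_index(list("A", "B", "A"), c("A", "B")), 0)
  # always together in every event containing either
  expect_equal(simple_ratio_index(list(c("A", "B"), c("A", "B"), "C"),
                                  c("A", "B")), 1)
  # never sampled at all
  expect_equal(simple_ratio_index(list("C", "C"), c("A", "B"),
                                  roster = c("A", "B", "C")), 0)
  expect_error(simple_ratio_index(parties, c("A", "Z")), "not in roster")
})

test_that("the SRI matrix equals a brute-force per-pair tally", {
  set.seed(31)
  roster <- LETTERS[1:5]
  parties <- replicate(30, sample(roster, sample(0:5, 1)), simplify = FALSE)
  net <- build_network(parties, roster)
  expect_equal(attr(net, "n_events"), sum(lengths(parties) > 0))
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_equal(net[i, j], oracle_sri(parties, roster[i], roster[j]))
    }
  }
})

test_that("SRI matrices are symmetric, zero-diagonal and within [0, 1]", {
  for (seed in 1:10) {
    set.seed(seed)
    roster <- letters[1:7]
    parties <- replicate(25, sample(roster, sample(0:7, 1)),
                         simplify = FALSE)
    net <- build_network(parties, roster)
    expect_true(isSymmetric(unclass(net)))
    expect_true(all(diag(net) == 0))
    expect_true(all(net >= 0 & net <= 1))
    # event order is irrelevant
    net2 <- build_network(parties[sample(length(parties))], roster)
    expect_equal(unclass(net2), unclass(net))
  }
})

test_that("events containing neither member of a dyad never change its SRI", {
  set.seed(5)
  roster <- letters[1:6]
  parties <- replicate(20, sample(roster, sample(1:6, 1)), simplify = FALSE)
  w0 <- simple_ratio_index(parties, c("a", "b"))
  with_extra <- c(parties, list(c("c", "d"), "e", character(0)))
  expect_equal(simple_ratio_index(with_extra, c("a", "b")), w0)
})

test_that("the sparser channel qualifies for fewer events", {
  dat <- simulate_community(sim_config(n_events = 300, seed = 21))
  ev <- group_events(dat$videos)
  roster <- select_shared_roster(dat$detections)
  qn <- function(ch) {
    attr(build_network(gambit_party(ev, dat$detections, ch), roster),
         "n_events")
  }
  expect_lte(qn("citizen"), qn("expert"))
})
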