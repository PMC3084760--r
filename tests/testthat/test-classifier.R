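test_that("an identical reference ranks first; ties break by subject id", {
  set.seed(51)
  target <- random_aa(60)
  other <- random_aa(60)
  rs <- tiny_refset(c(hit = target, miss = other), c("A1", "B"))
  hits <- rank_hits(target, rs)
  expect_equal(hits$subject_id[1], "hit")

  # two identical subjects: deterministic id tie-break
  rs2 <- tiny_refset(c(zeta = target, alpha = target), c("A1", "A1"))
  hits2 <- rank_hits(target, rs2)
  expect_equal(hits2$subject_id, c("alpha", "zeta"))
})

test_that("hit ranking equals an oracle sort of (evalue, score, id)", {
  set.seed(52)
  base <- random_aa(80)
  seqs <- vapply(1:10, function(i) {
    ch <- strsplit(base, "")[[1]]
    idx <- sample(80, sample(0:40, 1))
    for (p in idx) ch[p] <- sample(setdiff(AA20, ch[p]), 1)
    paste(ch, collapse = "")
  }, "")
  names(seqs) <- sprintf("ref%02d", 1:10)
  rs <- tiny_refset(seqs, rep(hco_types(), 2))
  hits <- rank_hits(base, rs)
  sc <- align_scoring()
  oracle <- do.call(rbind, lapply(names(seqs), function(id) {
    s <- oracle_local_score(base, seqs[[id]])
    data.frame(id = id, score = s,
               evalue = sc$K * nchar(base) * nchar(seqs[[id]]) * exp(-sc$lambda * s))
  }))
  oracle <- oracle[oracle$evalue <= sc$evalue_max, ]
  oracle <- oracle[order(oracle$evalue, -oracle$score, oracle$id), ]
  expect_equal(hits$subject_id, oracle$id)
  expect_equal(hits$score, oracle$score)
})

test_that("E-value acceptance: a weak best hit cannot classify", {
  set.seed(53)
  rs <- tiny_refset(c(r1 = random_aa(400), r2 = random_aa(400)), c("A1", "B"))
  res <- classify(random_aa(400), rs, mode = "top1", evalue_cutoff = 0.01)
  expect_equal(res$status, "no_hit")
  expect_equal(res$predicted, hco_unclassified())
})

test_that("top1 transfers the identical hit's label", {
  set.seed(54)
  a2 <- random_aa(120)
  rs <- tiny_refset(c(ra = a2, rb = random_aa(120)), c("A2", "NOR"))
  res <- classify(a2, rs, mode = "top1")
  expect_equal(res$predicted, "A2")
  expect_equal(res$status, "classified")
})

test_that("top-k disagreement among the first hits leaves the query unclassified", {
  set.seed(55)
  base <- random_aa(150)
  mutate_n <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    for (p in sample(length(ch), k)) ch[p] <- sample(setdiff(AA20, ch[p]), 1)
    paste(ch, collapse = "")
  }
  # three close references labeled B, B, C; one distant
  rs <- tiny_refset(c(h1 = mutate_n(base, 2), h2 = mutate_n(base, 4),
                      h3 = mutate_n(base, 6), far = random_aa(150)),
                    c("B", "B", "C", "A1"))
  res3 <- classify(base, rs, mode = "top3")
  expect_equal(res3$status, "unclassified")
  expect_equal(res3$predicted, hco_unclassified())
  # top2 sees only the agreeing B, B prefix
  res2 <- classify(base, rs, mode = "top2")
  expect_equal(res2$predicted, "B")
  # prefix disagreement persists for larger k
  res5 <- classify(base, rs, mode = "top5")
  expect_equal(res5$status, "unclassified")
})

test_that("leave-one-out on perfect twin families is a perfect tally", {
  set.seed(56)
  a1 <- random_aa(200); nor <- random_aa(200)
  rs <- tiny_refset(c(a = a1, b = a1, c = nor, d = nor),
                    c("A1", "A1", "NOR", "NOR"))
  tally <- leave_one_out(rs, mode = "top1")
  expect_equal(tally$counts["A1", "tp"], 2L)
  expect_equal(tally$counts["NOR", "tp"], 2L)
  expect_equal(sum(tally$counts$fp), 0L)
  expect_equal(sum(tally$counts$fn), 0L)
  expect_equal(tally$n_unclassified, 0L)
})

test_that("a mislabeled twin produces the hand-enumerated confusion", {
  set.seed(57)
  a1 <- random_aa(200); nor <- random_aa(200)
  # 'b' truly A1 but labeled NOR: each twin transfers the other's label
  rs <- tiny_refset(c(a = a1, b = a1, c = nor, d = nor),
                    c("A1", "NOR", "NOR", "NOR"))
  # A1 has a single member, which leave_one_out flags
  expect_warning(tally <- leave_one_out(rs, mode = "top1"), "single member")
  # a's best hit is b (NOR) -> Fp(NOR), Fn(A1); b's best hit is a (A1) ->
  # Fp(A1), Fn(NOR); c and d classify each other correctly as NOR
  expect_equal(tally$counts["A1", c("tp", "fp", "fn")],
               data.frame(tp = 0L, fp = 1L, fn = 1L, row.names = "A1"),
               ignore_attr = TRUE)
  expect_equal(tally$counts["NOR", "tp"], 2L)
  expect_equal(tally$counts["NOR", "fp"], 1L)
  expect_equal(tally$counts["NOR", "fn"], 1L)
})

test_that("leave-one-out equals an independent loop over classify()", {
  rs <- generate_gold_standard(per_type_n = 3, rate = 0.1, seed = 58)
  tally <- leave_one_out(rs, mode = "top1")
  truths <- character(0); preds <- character(0)
  for (i in seq_len(nrow(rs$records))) {
    rest_ids <- rs$records$id[-i]
    sub <- build_reference_set(rs$records[-i, ], rs$labels[rest_ids])
    res <- classify(rs$records$residues[i], sub, mode = "top1")
    truths <- c(truths, unname(rs$labels[rs$records$id[i]]))
    preds <- c(preds, res$predicted)
  }
  oracle <- confusion_tally(truths, preds)
  expect_equal(tally$counts, oracle$counts)
  # tally conservation: every query lands in Tp or Fn of its true type
  expect_equal(sum(tally$counts$tp) + sum(tally$counts$fn), nrow(rs$records))
})

test_that("top1 never reports agreement-based unclassified", {
  rs <- generate_gold_standard(per_type_n = 2, rate = 0.3, seed = 59,
                               protect_fingerprint = FALSE)
  tally <- leave_one_out(rs, mode = "top1")
  expect_true(all(tally$predictions$status %in% c("classified", "no_hit")))
})

test_that("precision and recall follow their defining ratios, NA when empty", {
  tally <- confusion_tally(
    truth = c(rep("A1", 5), rep("B", 5)),
    predicted = c(rep("A1", 5), rep("B", 3), "A1", "UNCLASSIFIED"))
  # A1: tp 5, fp 1; B: tp 3, fn 2 (one misclassified + one unclassified)
  expect_equal(precision(tally, "A1"), 5 / 6)
  expect_equal(recall(tally, "A1"), 1.0)
  expect_equal(precision(tally, "B"), 1.0)
  expect_equal(recall(tally, "B"), 0.6)
  expect_true(is.na(precision(tally, "C")))
  expect_true(is.na(recall(tally, "NOR")))

  g <- global_precision_recall(tally)
  expect_equal(g[["precision"]], 8 / 9)
  expect_equal(g[["recall"]], 8 / 10)
  expect_true(all(g >= 0 & g <= 1))

  perfect <- confusion_tally(rep("C", 4), rep("C", 4))
  expect_equal(unname(global_precision_recall(perfect)), c(1, 1))
  expect_equal(precision(perfect, "C"), 1.0)
})
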