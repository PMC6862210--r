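test_that("class profiles are arithmetic means with member counts", {
  fx <- toy_descriptors()
  prof <- compute_class_profiles(fx$desc, fx$ann)
  expect_equal(prof$class_id, c("1.1", "3.4", "non-enzyme"))
  expect_equal(prof$count, c(2L, 1L, 2L))
  expect_equal(prof$Tr3, c(2.0, 10.0, 0.55))
  expect_equal(prof$Tr5, c(3.0, 12.0, 0.75))

  expect_error(
    compute_class_profiles(fx$desc[1:2, ], fx$ann),
    "absent from descriptor table"
  )
})

test_that("a many-class synthetic set yields one profile per class", {
  d <- synth_generate(synth_spec(n_classes = 65L, sequences_per_class = 2L,
                                 n_nonenzymes = 5L,
                                 length_range = c(30L, 40L), seed = 9))
  desc <- descriptor_table(d$sequences, entropies = FALSE)
  prof <- compute_class_profiles(desc, d$annotations)
  expect_equal(nrow(prof), 66L)
  expect_equal(sum(prof$count), 135L)
  expect_equal(prof$count[prof$class_id == "non-enzyme"], 5L)
})

test_that("deviations subtract the class mean elementwise", {
  fx <- toy_descriptors()
  prof <- compute_class_profiles(fx$desc, fx$ann)
  p11 <- prof[prof$class_id == "1.1", ]

  expect_equal(deviation(c(Tr3 = 2.0, Tr5 = 3.0), p11),
               c(Tr3 = 0, Tr5 = 0))
  expect_equal(deviation(c(Tr3 = 5, Tr5 = 3), p11)[["Tr3"]], 3)
  # anti-symmetry about the mean
  x <- c(Tr3 = 4.5, Tr5 = 1.0)
  mirror <- c(Tr3 = 2 * 2.0 - 4.5, Tr5 = 2 * 3.0 - 1.0)
  expect_equal(deviation(x, p11), -deviation(mirror, p11))

  expect_error(deviation(c(Tr3 = 1), p11), "missing from x")
})

test_that("class members' deviations from their own profile average to zero", {
  d <- synth_generate(synth_spec(n_classes = 3L, sequences_per_class = 8L,
                                 n_nonenzymes = 0L,
                                 length_range = c(30L, 50L), seed = 5))
  desc <- descriptor_table(d$sequences)
  prof <- compute_class_profiles(desc, d$annotations)
  for (cl in prof$class_id) {
    members <- desc[d$annotations$class_id == cl, ]
    devs <- vapply(seq_len(nrow(members)), function(i) {
      deviation(members[i, ], prof[prof$class_id == cl, ])
    }, numeric(4))
    expect_equal(unname(rowMeans(devs)), rep(0, 4), tolerance = 1e-10)
  }
})

test_that("pair records respect the counting and labelling contracts", {
  fx <- toy_descriptors()
  prof <- compute_class_profiles(fx$desc, fx$ann)

  pairs <- make_pairs(fx$desc, fx$ann, prof, seed = 3)
  expect_equal(nrow(pairs), 5L)
  expect_equal(sum(pairs$label == 1L), 3L)
  expect_equal(names(pairs),
               c("sequence_id", "class_id", "Tr3_mean", "DTr3",
                 "Tr5_mean", "DTr5", "label"))
  # deviations are exact differences
  expect_equal(pairs$DTr3,
               fx$desc$Tr3[match(pairs$sequence_id, fx$desc$sequence_id)] -
                 prof$Tr3[match(pairs$class_id, prof$class_id)])

  expect_equal(make_pairs(fx$desc, fx$ann, prof, seed = 3), pairs)

  expect_error(make_pairs(fx$desc, fx$ann, prof, negative_policy = "nope"),
               "unknown negative_policy")
})

test_that("all-classes policy expands every non-enzyme combinatorially", {
  desc <- data.frame(sequence_id = c("n1", "n2"), Tr3 = c(1, 2),
                     Tr5 = c(1, 2))
  ann <- data.frame(sequence_id = c("n1", "n2"),
                    class_id = c("non-enzyme", "non-enzyme"))
  profiles <- data.frame(class_id = c("1.1", "2.1", "3.1", "4.1", "5.1"),
                         count = 1L, Tr3 = 1:5, Tr5 = 1:5)
  pairs <- make_pairs(desc, ann, profiles, negative_policy = "all-classes")
  expect_equal(nrow(pairs), 10L)
  expect_true(all(pairs$label == -1L))
})

test_that("cross-class policy adds one-vs-rest negatives for enzymes", {
  fx <- toy_descriptors()
  prof <- compute_class_profiles(fx$desc, fx$ann)
  pairs <- make_pairs(fx$desc, fx$ann, prof, negative_policy = "cross-class")
  # 3 enzymes x 2 classes + 2 non-enzymes x 2 classes
  expect_equal(nrow(pairs), 10L)
  expect_equal(sum(pairs$label == 1L), 3L)
  own <- pairs$sequence_id == "e1" & pairs$class_id == "1.1"
  expect_equal(pairs$label[own], 1L)
  other <- pairs$sequence_id == "e1" & pairs$class_id == "3.4"
  expect_equal(pairs$label[other], -1L)
})

test_that("subclass prediction follows argmax, threshold, and tie rules", {
  profiles <- data.frame(
    class_id = c("3.4", "5.2", "non-enzyme"),
    count = 1L,
    Tr3 = c(10, 2, 0.5), Tr5 = c(12, 3, 0.6)
  )
  # reward small deviations; all other class means sit far below x
  model <- linear_model(c(Tr3_mean = 0, Tr5_mean = 0,
                          DTr3 = -1, DTr5 = -1), intercept = 1)
  x <- c(Tr3 = 10, Tr5 = 12)  # exactly the 3.4 mean
  p <- predict_subclass(x, profiles, model)
  expect_equal(p$class_id, "3.4")
  expect_equal(p$score, 1)

  # hopeless intercept: everything scores negative
  never <- linear_model(c(Tr3_mean = 0, Tr5_mean = 0, DTr3 = 0, DTr5 = 0),
                        intercept = -1e6)
  expect_equal(predict_subclass(x, profiles, never)$class_id, "non-enzyme")

  # identical profiles tie -> lexicographically smaller EC string
  twins <- data.frame(class_id = c("2.7", "1.14"), count = 1L,
                      Tr3 = c(5, 5), Tr5 = c(5, 5))
  p2 <- predict_subclass(c(Tr3 = 5, Tr5 = 5), twins, model)
  expect_equal(p2$class_id, "1.14")

  expect_error(predict_subclass(x, profiles[3, ], model), "no enzyme class")
})
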