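test_that("token vocabulary is closed and pseudo tokens are distinct", {
  expect_error(gene_order(c("F", "XYZ")), "unknown gene symbol")
  ord <- parse_order_string("T,-P,CR:1100,F")
  expect_equal(ord$category, c("tRNA", "tRNA", "CR", "tRNA"))
  # pseudo-Pro is not tRNA-Pro
  a <- parse_order_string("T,-P,CR:1100")
  b <- parse_order_string("T,-P*,CR:1100")
  expect_false(same_arrangement(a, b))
  expect_equal(token_category("P*"), "pseudo")
  # NC tokens must carry a length
  expect_error(gene_order(c("F", "NC")), "NC tokens must carry")
})

test_that("order-string parsing handles strand and length markers", {
  ord <- parse_order_string("-Q")
  expect_equal(ord$strand, -1L)
  expect_equal(format_order_string(ord), "-Q")
  ord <- parse_order_string("CR:4110")
  expect_equal(ord$length_bp, 4110L)
  expect_error(parse_order_string(""), "empty order string")
  expect_error(parse_order_string("F,,V"), "malformed")
})

test_that("linearize anchors at tRNA-Phe, is idempotent and rotation-invariant", {
  ord <- type_order("III")
  lin <- linearize(ord)
  expect_equal(lin$name[1:4], c("F", "12S", "V", "16S"))
  expect_identical(linearize(lin), lin)
  set.seed(41)
  for (i in 1:25) {
    rot <- rotate_any(ord)
    expect_identical(linearize(rot)$name, lin$name)
  }
  no_f <- ord[ord$name != "F", ]
  class(no_f) <- class(ord)
  expect_error(linearize(no_f, "F"), "12S")
})

test_that("canonical keys are rotation-invariant and separate the types", {
  reg <- test_registry()
  ord3 <- type_order("III")
  key3 <- canonical_key(ord3)
  set.seed(7)
  for (i in 1:25) expect_identical(canonical_key(rotate_any(ord3)), key3)
  # III-C differs from III by its extra pseudo-Pro
  expect_false(identical(key3, canonical_key(type_order("III-C"))))
  # Type I differs from Type II by Gln inside the WANCY cluster
  expect_false(identical(canonical_key(type_order("I")),
                         canonical_key(type_order("II"))))
  # III-E is token-identical to III (separated by the asymmetry marker)
  expect_identical(key3, canonical_key(type_order("III-E")))
  # with lengths compared, III-E is distinct
  expect_false(identical(canonical_key(ord3, compare_lengths = TRUE),
                         canonical_key(type_order("III-E"), compare_lengths = TRUE)))
})

test_that("same_arrangement is an equivalence relation on random orders", {
  set.seed(11)
  for (i in 1:40) {
    x <- random_order()
    y <- rotate_any(x)
    z <- rotate_any(y)
    expect_true(same_arrangement(x, x))
    expect_true(same_arrangement(x, y))
    expect_true(same_arrangement(y, x))
    expect_true(same_arrangement(x, z) == (same_arrangement(x, y) && same_arrangement(y, z)))
  }
  # strand is part of identity: a gene flipped to the other strand is a
  # different arrangement
  x <- parse_order_string("F,12S,V,16S")
  y <- parse_order_string("F,12S,-V,16S")
  expect_false(same_arrangement(x, y))
})
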