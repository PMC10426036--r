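test_that("13-digit brand codes parse through the slot grammar", {
  reg <- tiny_registry()
  b <- parse_brand_code("AB0CD1______2", reg)
  expect_equal(b$symbols, c("circle", "slash"))
  expect_equal(b$rotations, c(0, 45))
  expect_equal(b$location, "2")

  b4 <- parse_brand_code("AB0AB0AB0AB02", reg)
  expect_equal(b4$symbols, rep("circle", 4))

  expect_error(parse_brand_code("____________2", reg), "empty")
  expect_error(parse_brand_code("XX0CD1______2", reg), "slot 1")
  expect_error(parse_brand_code("AB0CD1______", reg), "13-character")
})

test_that("redundant abbreviations canonicalise to one symbol with offsets", {
  reg <- component_registry(c("BS", "FS"), c("slash", "slash"),
                            offset_degrees = c(0, 90))
  a <- canonicalize("BS", 0, reg)
  b <- canonicalize("FS", 0, reg)
  expect_equal(a$symbol, b$symbol)
  expect_equal(a$rotation, 0)
  expect_equal(b$rotation, 90)
  expect_equal(canonicalize("BS", 7, reg)$rotation, 315)
  expect_error(canonicalize("ZZ", 0, reg), "unknown")
  expect_error(component_registry("AB", "x", offset_degrees = 360),
               "\\[0, 360\\)")
})

test_that("serialisation inverts parsing on expressible brands", {
  reg <- synthetic_registry(10)
  set.seed(4)
  for (i in 1:25) {
    k <- sample(1:4, 1)
    b <- structure(list(
      symbols = sprintf("S%03d", sample.int(10, k, replace = TRUE)),
      rotations = sample(0:7, k, replace = TRUE) * 45,
      location = as.character(sample(0:9, 1))), class = "brand")
    code <- serialize_brand_code(b, reg)
    expect_equal(nchar(code), 13L)
    b2 <- parse_brand_code(code, reg)
    expect_equal(b2$symbols, b$symbols)
    expect_equal(b2$rotations, b$rotations)
    expect_equal(b2$location, b$location)
  }
})

test_that("deduplication removes duplicates within, not across, zips", {
  df <- data.frame(code13 = c("X", "X", "X", "Y"),
                   zip = c("z1", "z1", "z2", "z1"),
                   first_year = c(1995L, 1990L, 1992L, 1990L))
  out <- deduplicate(df)
  expect_equal(nrow(out), 3L)
  # retained instance within z1 is the earliest first_year
  expect_equal(out$first_year[out$code13 == "X" & out$zip == "z1"], 1990L)
  expect_true("z2" %in% out$zip[out$code13 == "X"])

  expect_equal(nrow(deduplicate(df[0, ])), 0L)
  expect_identical(deduplicate(out), out)  # idempotent

  set.seed(9)
  rnd <- data.frame(code13 = sample(LETTERS[1:5], 40, replace = TRUE),
                    zip = sample(c("z1", "z2"), 40, replace = TRUE))
  d1 <- deduplicate(rnd)
  expect_lte(nrow(d1), nrow(rnd))
  expect_identical(deduplicate(d1), d1)
})

test_that("populations round-trip through CSV and JSON", {
  reg <- synthetic_registry(12)
  spatial <- spatial_registry(c("z1", "z2"), c("c1", "c2"), c("NW", "SE"))
  pop <- brand_population(
    rbind(c(1L, 2L, 0L, 0L), c(3L, 3L, 4L, 0L), c(5L, 0L, 0L, 0L)),
    c("z1", "z2", "z1"), c(1990L, 1992L, 1991L), NA_integer_, 1995L,
    registry_symbols <- sprintf("S%03d", 1:12), spatial,
    rotations = rbind(c(45, 90, 0, 0), c(0, 0, 315, 0), c(135, 0, 0, 0)))
  for (fmt in c("csv", "json")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_population(pop, path, fmt, reg)
    pop2 <- read_population(path, fmt, reg, spatial)
    expect_equal(pop2$components, pop$components)
    expect_equal(pop2$rotations, pop$rotations)
    expect_equal(pop2$zip, pop$zip)
    expect_equal(pop2$first_year, pop$first_year)
    expect_equal(pop2$year, pop$year)
  }
})

test_that("schema violations are reported with their row", {
  reg <- synthetic_registry(5)
  spatial <- spatial_registry("z1", "c1", "NW")
  path <- tempfile(fileext = ".csv")
  writeLines(c("code13,zip,book_year",
               "A00B00______1,z1,1995",
               "A00B00_____1,z1,1995"), path)
  expect_error(read_population(path, "csv", reg, spatial), "row 3|row 2")

  path2 <- tempfile(fileext = ".csv")
  writeLines(c("code13,zip,book_year", "A00B00______1,z9,1995"), path2)
  expect_error(read_population(path2, "csv", reg, spatial), "z9")
})

test_that("registry and spatial files round-trip", {
  reg <- component_registry(c("BS", "FS"), c("slash", "slash"), c(0, 90))
  p <- tempfile(fileext = ".csv")
  write_registry(reg, p)
  reg2 <- read_registry(p)
  expect_equal(as.data.frame(reg2), as.data.frame(reg))

  sp <- synthetic_spatial(10)
  p2 <- tempfile(fileext = ".csv")
  write_spatial(sp, p2)
  sp2 <- read_spatial(p2)
  expect_equal(sp2$zip, sp$zip)
  expect_equal(sp2$quadrant, sp$quadrant)
  expect_error(spatial_registry("z1", "c1", "XX"), "NW/NE/SW/SE")
})
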