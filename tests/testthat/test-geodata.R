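test_that("village construction enforces geometry and population invariants", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  v <- villages("v1", "One", list(sq), 100L)
  expect_equal(nrow(v), 1)
  expect_equal(v$population, 100L)
  expect_equal(c(v$cx, v$cy), c(0.5, 0.5))
  expect_equal(v$area_km2, 1)
  expect_error(villages("v1", "One", list(sq), -5L), "non-negative")
  degenerate <- rbind(c(0, 0), c(1, 0), c(2, 0))
  expect_error(villages("v1", "One", list(degenerate), 10L), "area")
})

test_that("road validation enforces type, width and service invariants", {
  line <- cbind(c(0, 1), c(0, 0))
  expect_error(roads("s1", list(line), "gravel", 8), "road_type.*s1")
  expect_error(roads("s1", list(line), "waterway", 8), "width_ft")
  expect_error(roads("s1", list(line), "unpaved", 8,
                     fixed_route_modes = list("tempo")), "paved")
  r <- roads("s1", list(line), "paved", 12, list("tempo"))
  expect_equal(r$length_km, 1)
})

test_that("geodata layers survive a write/read round trip field-for-field", {
  dir <- withr::local_tempdir()
  sc <- generate_scenario(scenario_config(seed = 7))
  paths <- list(
    villages = file.path(dir, "villages.geojson"),
    roads = file.path(dir, "roads.geojson"),
    hubs = file.path(dir, "hubs.geojson"),
    facilities = file.path(dir, "facilities.geojson"),
    constraints = file.path(dir, "constraints.geojson"))
  for (k in names(paths)) write_geodata(sc[[k]], paths[[k]])
  vil2 <- read_geodata(paths$villages, "villages")
  expect_equal(vil2$village_id, sc$villages$village_id)
  expect_equal(vil2$population, sc$villages$population)
  expect_equal(vil2$boundary, lapply(sc$villages$boundary, unname),
               tolerance = 1e-12)
  expect_equal(vil2$cx, sc$villages$cx, tolerance = 1e-12)
  rd2 <- read_geodata(paths$roads, "roads")
  expect_equal(rd2$segment_id, sc$roads$segment_id)
  expect_equal(rd2$road_type, sc$roads$road_type)
  expect_equal(rd2$length_km, sc$roads$length_km, tolerance = 1e-12)
  expect_equal(rd2$fixed_route_modes, sc$roads$fixed_route_modes)
  hb2 <- read_geodata(paths$hubs, "hubs")
  expect_equal(hb2$hub_id, sc$hubs$hub_id)
  expect_equal(hb2$kind, sc$hubs$kind)
  fc2 <- read_geodata(paths$facilities, "facilities")
  expect_equal(fc2$facility_id, sc$facilities$facility_id)
  cs2 <- read_geodata(paths$constraints, "constraints")
  expect_equal(cs2$effect, sc$constraints$effect)
  # writing the re-read layer reproduces the file byte-for-byte
  write_geodata(vil2, file.path(dir, "villages2.geojson"))
  expect_identical(readLines(paths$villages),
                   readLines(file.path(dir, "villages2.geojson")))
})

test_that("schema and coordinate-system violations are rejected by name", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "bad.geojson")
  # missing required property names the feature
  obj <- list(type = "FeatureCollection",
              metadata = list(coordinate_system = "planar_km"),
              features = list(list(
                type = "Feature",
                geometry = list(type = "Point", coordinates = c(1, 2)),
                properties = list(hub_id = "h9", name = "x"))))
  jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA)
  expect_error(read_geodata(p, "hubs"), "h9.*kind")
  # unknown road_type in an otherwise valid file
  rd <- roads("s1", list(cbind(c(0, 1), c(0, 0))), "paved", 8)
  write_geodata(rd, p)
  txt <- gsub('"paved"', '"gravel"', readLines(p))
  writeLines(txt, p)
  expect_error(read_geodata(p, "roads"), "road_type")
  # missing planar metadata (e.g. raw lon/lat exports) is a hard error
  obj$metadata <- NULL
  jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA)
  expect_error(read_geodata(p, "hubs"), "coordinate-system")
  expect_error(write_geodata(rd[0, ], file.path(dir, "empty.geojson")),
               "empty")
})

test_that("call-log reading validates dates and the usage implication chain", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "calls.csv")
  ok <- tibble::tibble(
    call_id = sprintf("c%d", 1:5),
    date = as.Date(c("2013-10-02", "2014-05-01", "2014-12-31", "2015-04-01",
                     "2015-09-29")),
    village_id = "v1", referred = c(1L, 1L, 1L, 0L, 1L),
    complied = c(1L, 0L, 1L, NA, 1L), used_transport = c(1L, NA, 0L, NA, NA))
  readr::write_csv(ok, p)
  got <- read_call_log(p)
  expect_equal(nrow(got), 5)
  expect_equal(got$semester, c(1L, 2L, 3L, 4L, 4L))
  expect_true(all(got$used_transport <= got$complied))
  expect_true(all(got$complied <= got$referred))
  # out-of-window date
  bad <- ok; bad$date[1] <- as.Date("2013-09-30")
  readr::write_csv(bad, p)
  expect_error(read_call_log(p), "range error")
  # transport use without compliance
  bad <- ok; bad$complied[1] <- 0L
  readr::write_csv(bad, p)
  expect_error(read_call_log(p), "consistency error")
  # unresolvable villages are dropped with a message and a logged count
  unk <- ok; unk$village_id[2] <- "unknown"
  readr::write_csv(unk, p)
  expect_message(got <- read_call_log(p), "1 call")
  expect_equal(nrow(got), 4)
  expect_equal(attr(got, "dropped_unknown_village"), 1L)
})

test_that("the expanded call-log fixture matches the published call volume", {
  cl <- call_log_fixture()
  expect_equal(nrow(cl), 4830)
  expect_equal(sum(cl$village_id == "unknown"), 9)
  valid <- cl[cl$village_id != "unknown", ]
  expect_equal(sum(valid$referred), 2731)
  # read_call_log round trip drops exactly the unresolvable nine
  dir <- withr::local_tempdir()
  p <- file.path(dir, "log.csv")
  write_call_log(cl, p)
  expect_message(got <- read_call_log(p), "9 call")
  expect_equal(nrow(got), 4821)
  expect_equal(sum(got$referred), 2731)
})
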