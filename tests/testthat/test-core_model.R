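# Domain types, invariants and the on-disk container.

test_that("sweep and record constructors enforce their invariants", {
  expect_error(voltage_sweep(numeric(0)), "non-empty")
  expect_error(voltage_sweep(c(-65, NaN)), "finite")
  expect_error(voltage_sweep(rep(-65, 100), kind = "evoked_cs"),
               "stim_onset")
  expect_error(voltage_sweep(rep(-65, 100), stim_onset = 5), "stim_onset")
  # evoked sweeps need 1 s on both sides of the stimulus
  expect_error(voltage_sweep(rep(-65, 15000), stim_onset = 500,
                             kind = "evoked_cs"), "pre-stimulus")
  expect_error(voltage_sweep(rep(-65, 15000), stim_onset = 1000,
                             kind = "evoked_cs"), "post-stimulus")
  ok <- voltage_sweep(rep(-65, 20000), stim_onset = 1000, kind = "evoked_cs")
  expect_equal(sweep_duration_ms(ok), 2000)

  sw <- voltage_sweep(rep(-65, 100))
  expect_error(neuron_record("a", sweeps = list(
    sw, voltage_sweep(rep(-65, 100), sample_rate = 5000))),
    "sample_rate")
  expect_error(
    ephys_dataset(list(neuron_record("a", sweeps = list(sw)),
                       neuron_record("a", sweeps = list(sw)))),
    "unique")
})

test_that("dataset container round-trips through disk exactly", {
  d <- simulate_dataset(tiny_cfg(seed = 7))
  path <- withr::local_tempdir()
  write_dataset(d, path)
  d2 <- read_dataset(path)

  expect_identical(names(d2$neurons), names(d$neurons))
  for (id in names(d$neurons)) {
    a <- d$neurons[[id]]; b <- d2$neurons[[id]]
    expect_identical(b$condition, a$condition)
    expect_identical(b$opsin, a$opsin)
    expect_equal(length(b$sweeps), length(a$sweeps))
    for (i in seq_along(a$sweeps)) {
      expect_identical(b$sweeps[[i]]$kind, a$sweeps[[i]]$kind)
      expect_equal(b$sweeps[[i]]$samples, a$sweeps[[i]]$samples,
                   tolerance = 1e-6)
      expect_equal(length(b$sweeps[[i]]$samples),
                   length(a$sweeps[[i]]$samples))
    }
  }
  expect_equal(d2$provenance$seed, 7)
  expect_equal(length(d2$probes), length(d$probes))
  expect_equal(d2$probes[[1]]$trials[[1]]$post,
               d$probes[[1]]$trials[[1]]$post, tolerance = 1e-6)
  expect_equal(d2$params$spont_threshold_mV, d$params$spont_threshold_mV)

  # two writes produce byte-identical metadata sidecars
  p2 <- withr::local_tempdir()
  write_dataset(d, p2)
  expect_identical(readLines(file.path(path, "dataset.json")),
                   readLines(file.path(p2, "dataset.json")))

  # a corrupted sweep column is a validation error naming the sweep
  f <- file.path(path, "sweeps", paste0(names(d$neurons)[1], ".csv"))
  mat <- readr::read_csv(f, show_col_types = FALSE)
  readr::write_csv(mat[-1, ], f)
  expect_error(read_dataset(path), "s1")
  expect_error(read_dataset(withr::local_tempdir()), "sidecar")
})

test_that("validate_dataset reports findings without throwing", {
  d <- simulate_dataset(tiny_cfg())
  f <- validate_dataset(d)
  # structural invariants hold; the 40 s records trip the 5-minute warning
  # and the printed 440 ms train disagrees with the pulse arithmetic
  expect_false(any(f$severity == "error"))
  expect_true("short_spontaneous_record" %in% f$rule)
  expect_true("red_train_nominal_mismatch" %in% f$rule)
  # pure: repeated calls give identical findings
  expect_identical(f, validate_dataset(d))

  # a full-length record raises no short-record warning
  cfg <- tiny_cfg()
  n_ok <- generate_neuron(cfg, "early", with_spont = FALSE)
  d_ok <- ephys_dataset(list(n_ok))
  expect_false("short_spontaneous_record" %in% validate_dataset(d_ok)$rule)

  # three neurons sharing one pair_id
  sw <- voltage_sweep(rep(-65, 100))
  trio <- lapply(c("a", "b", "c"), function(id)
    neuron_record(id, sweeps = list(sw), pair_id = "p"))
  expect_true("pair_cardinality" %in% validate_dataset(
    ephys_dataset(trio))$rule)
})

test_that("half-open window arithmetic addresses samples exactly", {
  # at 10 kHz, [0, 1000) is exactly 10000 samples starting at index 1
  idx <- replaytrace:::window_idx(25000, 10000, 0, 1000)
  expect_identical(idx, 1:10000)
  # [1000, 2000) starts at the sample AT 1000 ms
  idx2 <- replaytrace:::window_idx(25000, 10000, 1000, 2000)
  expect_identical(idx2[1], 10001L)
  expect_identical(length(idx2), 10000L)
})
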