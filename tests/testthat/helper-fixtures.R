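# Small masks and cohorts shared across tests. Everything is generated in
# code; nothing is read from disk.

tiny_mask1 <- function() make_fixture_mask(96, 64, "one_panel")
tiny_mask2 <- function() make_fixture_mask(96, 128, "two_panel")

# A small simulated cohort on small masks; arguments forwarded to sim_config.
tiny_config <- function(n_patients = 6, n_control_pool = 12,
                        subgroup_counts = c(CRPS = 2, NP = 1, FM = 1,
                                            LBP = 1, other = 1),
                        tasks = all_tasks(), seed = 42, ...) {
  sim_config(n_patients = n_patients, n_control_pool = n_control_pool,
             subgroup_counts = subgroup_counts,
             one_panel_dim = c(96, 64), two_panel_dim = c(96, 128),
             tasks = tasks, seed = seed, ...)
}

# A response built from an explicit full-grid matrix.
matrix_response <- function(mat, mask, task = "pain_current", id = "X1",
                            intentional_empty = NA) {
  colouring_response(id, task, mat, mask, intentional_empty)
}

# Minimal participant row factory (all scales zero unless overridden).
participant_row <- function(id, group = "control", subgroup = "none",
                            age = 40, gender = "woman",
                            chronic_pain_flag = FALSE, nrs_now = 0,
                            bpi_now = 0, bpi_24h_mean = 0, ...) {
  row <- data.frame(id = id, group = group, subgroup = subgroup,
                    affected_side = "none", age = age, gender = gender,
                    chronic_pain_flag = chronic_pain_flag,
                    nrs_now = nrs_now, bpi_now = bpi_now,
                    bpi_24h_mean = bpi_24h_mean,
                    stringsAsFactors = FALSE)
  for (col in c(bodymaps:::BPI_ITEMS, bodymaps:::SELF_RATING_ITEMS))
    row[[col]] <- 0
  extra <- list(...)
  for (nm in names(extra)) row[[nm]] <- extra[[nm]]
  row
}

participant_table <- function(...) do.call(rbind, list(...))
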