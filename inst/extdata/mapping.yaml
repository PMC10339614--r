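# Study-dialect mapping configuration.
#
# One block per contributing study. `columns` maps common-data-model (CDM)
# variable names to that study's extract column names, per table; a CDM
# variable with no entry is structurally unavailable in that study and is
# never invented. `values` maps source codes to CDM codes; unknown source
# codes are errors, never silently coerced. Granularity is reduced to the
# most inclusive shared coding (e.g. detailed ethnic groups collapse to
# Caucasian / Non-Caucasian).
#
# `availability` is the per-study variable-availability matrix; `unavailable`
# lists the (study, variable) pairs a study never collected. The column maps
# must agree with it (checked at load time).

availability:
  unavailable:
    BCRD: [date_of_symptom_onset, route]
    BSPAR-Et: [date_of_symptom_onset, route]
    CAPS: [date_of_diagnosis]
    CHARMS: [date_of_diagnosis, pain_vas, stop_reason]

drug_classes:
  MTX: [Methotrexate]
  TNFi: [Etanercept, Adalimumab, Infliximab]
  other-biologic: [Tocilizumab, Abatacept]

studies:
  BCRD:
    identifier_column: nhs_no
    columns:
      records:
        local_patient_id: patient_id
        nhs_number: nhs_no
        entry_date: reg_date
        date_of_birth: dob
        gender: sex
        ethnicity: ethnic_origin
        ilar_subtype: ilar_category
        date_of_diagnosis: diagnosis_date
        ana: ana_status
        rf: rf_status
        hla_b27: hla_b27_status
        uveitis_ever: uveitis
      visits:
        visit_date: visit_dt
        ajc: active_jts
        ljc: limited_jts
        chaq: chaq_score
        esr: esr
        crp: crp
        pga: phys_global
        pge: parent_global
        pain_vas: pain_score
        height_cm: height
        weight_kg: weight
      episodes:
        drug: drug_name
        start_date: start_dt
        stop_date: stop_dt
        dose: dose_mg
        stop_reason: stop_reason
    values:
      gender: {M: male, F: female}
      ethnicity:
        White: Caucasian
        Asian: Non-Caucasian
        Black: Non-Caucasian
        Mixed: Non-Caucasian
        Other: Non-Caucasian
      ilar_subtype:
        Systemic arthritis: systemic
        Persistent oligoarthritis: oligo-persistent
        Extended oligoarthritis: oligo-extended
        RF negative polyarthritis: poly RF-
        RF positive polyarthritis: poly RF+
        Enthesitis related arthritis: enthesitis-related
        Psoriatic arthritis: psoriatic
        Undifferentiated arthritis: undifferentiated
      ana: {Positive: positive, Negative: negative}
      rf: {Positive: positive, Negative: negative}
      hla_b27: {Positive: positive, Negative: negative}
      uveitis_ever: {"Yes": "yes", "No": "no"}
      stop_reason:
        Ineffectiveness: ineffective
        Adverse event: adverse-event
        Disease remission: remission
        Other: other

  BSPAR-Et:
    identifier_column: nhsnumber
    columns:
      records:
        local_patient_id: regno
        nhs_number: nhsnumber
        entry_date: date_reg
        date_of_birth: date_birth
        gender: gender
        ethnicity: ethnicity
        ilar_subtype: ilar
        date_of_diagnosis: date_diag
        ana: ana
        rf: rf
        hla_b27: b27
        uveitis_ever: uveitis_ever
      visits:
        visit_date: date_seen
        ajc: ajc
        ljc: ljc
        chaq: chaq
        esr: esr_mm_hr
        crp: crp_mg_l
        pga: pga_vas
        pge: pge_vas
        pain_vas: pain_vas
        height_cm: height_cm
        weight_kg: weight_kg
      episodes:
        drug: drug
        start_date: date_started
        stop_date: date_stopped
        dose: dose
        stop_reason: reason_stopped
    values:
      gender: {"1": male, "2": female}
      ethnicity: {Caucasian: Caucasian, Non-Caucasian: Non-Caucasian}
      ilar_subtype:
        "1": systemic
        "2": oligo-persistent
        "3": oligo-extended
        "4": poly RF-
        "5": poly RF+
        "6": enthesitis-related
        "7": psoriatic
        "8": undifferentiated
      ana: {"1": positive, "0": negative}
      rf: {"1": positive, "0": negative}
      hla_b27: {"1": positive, "0": negative}
      uveitis_ever: {"1": "yes", "0": "no"}
      stop_reason: {INEFF: ineffective, AE: adverse-event, REM: remission, OTH: other}

  CAPS:
    identifier_column: nhs_number
    columns:
      records:
        local_patient_id: caps_id
        nhs_number: nhs_number
        entry_date: date_joined
        date_of_birth: date_of_birth
        gender: sex
        ethnicity: ethnic_group
        ilar_subtype: ilar_subtype
        date_of_symptom_onset: symptom_onset_date
        ana: ana_result
        rf: rf_result
        hla_b27: hla_b27
        uveitis_ever: uveitis
      visits:
        visit_date: visit_date
        ajc: active_joint_count
        ljc: limited_joint_count
        chaq: chaq
        esr: esr
        crp: crp
        pga: pga
        pge: pge
        pain_vas: pain_vas
        height_cm: height
        weight_kg: weight
      episodes:
        drug: medication
        start_date: med_start
        stop_date: med_stop
        route: route
        dose: dose
        stop_reason: reason_for_stopping
    values:
      gender: {Male: male, Female: female}
      ethnicity:
        White British: Caucasian
        White Other: Caucasian
        Indian: Non-Caucasian
        Pakistani: Non-Caucasian
        Bangladeshi: Non-Caucasian
        Black Caribbean: Non-Caucasian
        Black African: Non-Caucasian
        Chinese: Non-Caucasian
        Mixed: Non-Caucasian
        Other: Non-Caucasian
      ilar_subtype:
        Systemic: systemic
        Oligoarthritis persistent: oligo-persistent
        Oligoarthritis extended: oligo-extended
        Polyarthritis RF negative: poly RF-
        Polyarthritis RF positive: poly RF+
        Enthesitis related: enthesitis-related
        Psoriatic: psoriatic
        Undifferentiated: undifferentiated
      ana: {POS: positive, NEG: negative}
      rf: {POS: positive, NEG: negative}
      hla_b27: {POS: positive, NEG: negative}
      uveitis_ever: {Ever: "yes", Never: "no"}
      route: {Oral: oral, SC: subcutaneous}
      stop_reason:
        Inefficacy: ineffective
        Adverse reaction: adverse-event
        Remission: remission
        Other reason: other

  CHARMS:
    identifier_column: nhs
    columns:
      records:
        local_patient_id: charms_no
        nhs_number: nhs
        entry_date: reg_date
        date_of_birth: dob
        gender: gender
        ethnicity: ethnicity
        ilar_subtype: jia_subtype
        date_of_symptom_onset: onset_date
        ana: ana
        rf: rf
        hla_b27: hlab27
        uveitis_ever: uveitis
      visits:
        visit_date: assess_date
        ajc: ajc
        ljc: ljc
        chaq: chaq
        esr: esr
        crp: crp
        pga: pga
        pge: pge
        height_cm: height
        weight_kg: weight
      episodes:
        drug: drug
        start_date: start_date
        stop_date: stop_date
        route: route
        dose: dose
    values:
      gender: {M: male, F: female}
      ethnicity:
        White: Caucasian
        South Asian: Non-Caucasian
        Black: Non-Caucasian
        East Asian: Non-Caucasian
        Mixed: Non-Caucasian
        Other: Non-Caucasian
      ilar_subtype:
        Systemic JIA: systemic
        Oligo persistent: oligo-persistent
        Oligo extended: oligo-extended
        Poly RF neg: poly RF-
        Poly RF pos: poly RF+
        ERA: enthesitis-related
        Psoriatic JIA: psoriatic
        Undifferentiated JIA: undifferentiated
      ana: {"Y": positive, "N": negative}
      rf: {"Y": positive, "N": negative}
      hla_b27: {"Y": positive, "N": negative}
      uveitis_ever: {"Y": "yes", "N": "no"}
      route: {PO: oral, SC: subcutaneous}
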