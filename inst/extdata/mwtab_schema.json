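{
  "STUDY": {
    "required": ["STUDY_TITLE", "STUDY_SUMMARY", "INSTITUTE", "LAST_NAME",
                 "FIRST_NAME", "ADDRESS", "EMAIL", "PHONE"],
    "optional": ["STUDY_TYPE", "DEPARTMENT", "LABORATORY", "SUBMIT_DATE",
                 "NUM_GROUPS", "TOTAL_SUBJECTS", "STUDY_COMMENTS",
                 "PUBLICATIONS"],
    "rules": {
      "EMAIL": {"regex": "^[^@\\s]+@[^@\\s]+\\.[^@\\s]+$"},
      "PHONE": {"regex": "^[0-9+() .-]{7,}$"}
    }
  },
  "SUBJECT": {
    "required": ["SUBJECT_TYPE", "SUBJECT_SPECIES"],
    "optional": ["TAXONOMY_ID", "GENOTYPE_STRAIN", "AGE_OR_AGE_RANGE",
                 "WEIGHT_OR_WEIGHT_RANGE", "HEIGHT_OR_HEIGHT_RANGE",
                 "GENDER", "SPECIES_GROUP", "ANIMAL_ANIMAL_SUPPLIER",
                 "ANIMAL_HOUSING", "ANIMAL_LIGHT_CYCLE", "ANIMAL_FEED",
                 "ANIMAL_WATER", "CELL_BIOSOURCE_OR_SUPPLIER",
                 "CELL_STRAIN_DETAILS", "SUBJECT_COMMENTS"]
  },
  "COLLECTION": {
    "required": ["COLLECTION_SUMMARY"],
    "optional": ["COLLECTION_PROTOCOL_ID", "COLLECTION_PROTOCOL_FILENAME",
                 "COLLECTION_PROTOCOL_COMMENTS", "SAMPLE_TYPE",
                 "COLLECTION_METHOD", "COLLECTION_LOCATION", "COLLECTION_FREQUENCY",
                 "COLLECTION_DURATION", "COLLECTION_TIME", "VOLUMEORAMOUNT_COLLECTED",
                 "STORAGE_CONDITIONS", "COLLECTION_VIALS", "STORAGE_VIALS",
                 "COLLECTION_TUBE_TEMP", "ADDITIVES"]
  },
  "TREATMENT": {
    "required": ["TREATMENT_SUMMARY"],
    "optional": ["TREATMENT_PROTOCOL_ID", "TREATMENT_PROTOCOL_FILENAME",
                 "TREATMENT_PROTOCOL_COMMENTS", "TREATMENT", "TREATMENT_COMPOUND",
                 "TREATMENT_ROUTE", "TREATMENT_DOSE", "TREATMENT_DOSEVOLUME",
                 "TREATMENT_DOSEDURATION", "TREATMENT_VEHICLE", "ANIMAL_VET_TREATMENTS",
                 "ANIMAL_ANESTHESIA", "ANIMAL_ACCLIMATION_DURATION",
                 "ANIMAL_FASTING", "ANIMAL_ENDP_EUTHANASIA"]
  },
  "SAMPLEPREP": {
    "required": ["SAMPLEPREP_SUMMARY"],
    "optional": ["SAMPLEPREP_PROTOCOL_ID", "SAMPLEPREP_PROTOCOL_FILENAME",
                 "SAMPLEPREP_PROTOCOL_COMMENTS", "PROCESSING_METHOD",
                 "PROCESSING_STORAGE_CONDITIONS", "EXTRACTION_METHOD",
                 "EXTRACT_CONCENTRATION_DILUTION", "EXTRACT_ENRICHMENT",
                 "EXTRACT_CLEANUP", "EXTRACT_STORAGE", "SAMPLE_RESUSPENSION",
                 "SAMPLE_DERIVATIZATION", "SAMPLE_SPIKING"]
  },
  "CHROMATOGRAPHY": {
    "required": ["CHROMATOGRAPHY_TYPE", "INSTRUMENT_NAME", "COLUMN_NAME"],
    "optional": ["CHROMATOGRAPHY_SUMMARY", "FLOW_GRADIENT", "FLOW_RATE",
                 "COLUMN_TEMPERATURE", "METHODS_FILENAME", "SOLVENT_A",
                 "SOLVENT_B", "METHODS_ID", "METHODS_PROVIDER", "CHROMATOGRAPHY_COMMENTS",
                 "INJECTION_TEMPERATURE", "INTERNAL_STANDARD", "RETENTION_INDEX",
                 "RETENTION_TIME", "SAMPLE_INJECTION", "WASHING_BUFFER"]
  },
  "ANALYSIS": {
    "required": ["ANALYSIS_TYPE"],
    "optional": ["LABORATORY_NAME", "OPERATOR_NAME", "DETECTOR_TYPE",
                 "SOFTWARE_VERSION", "ACQUISITION_DATE", "ANALYSIS_PROTOCOL_FILE",
                 "ACQUISITION_PARAMETERS_FILE", "PROCESSING_PARAMETERS_FILE",
                 "DATA_FORMAT", "ANALYSIS_COMMENTS"]
  },
  "MS": {
    "required": ["INSTRUMENT_NAME", "INSTRUMENT_TYPE", "MS_TYPE", "ION_MODE"],
    "optional": ["MS_COMMENTS", "CAPILLARY_TEMPERATURE", "CAPILLARY_VOLTAGE",
                 "COLLISION_ENERGY", "COLLISION_GAS", "DRY_GAS_FLOW", "DRY_GAS_TEMP",
                 "FRAGMENT_VOLTAGE", "FRAGMENTATION_METHOD", "GAS_PRESSURE",
                 "HELIUM_FLOW", "ION_SOURCE_TEMPERATURE", "ION_SPRAY_VOLTAGE",
                 "IONIZATION", "IONIZATION_ENERGY", "IONIZATION_POTENTIAL",
                 "MASS_ACCURACY", "PRECURSOR_TYPE", "REAGENT_GAS", "RESOLUTION_SETTING",
                 "SCAN_RANGE_MOVERZ", "SCANNING_CYCLE", "SCANNING_RANGE",
                 "SKIMMER_VOLTAGE", "TUBE_LENS_VOLTAGE", "MS_RESULTS_FILE"]
  },
  "NMR": {
    "required": ["INSTRUMENT_NAME", "INSTRUMENT_TYPE", "NMR_EXPERIMENT_TYPE",
                 "SPECTROMETER_FREQUENCY"],
    "optional": ["NMR_COMMENTS", "FIELD_FREQUENCY_LOCK", "STANDARD_CONCENTRATION",
                 "NMR_PROBE", "NMR_SOLVENT", "NMR_TUBE_SIZE", "SHIMMING_METHOD",
                 "PULSE_SEQUENCE", "WATER_SUPPRESSION", "PULSE_WIDTH",
                 "POWER_LEVEL", "RECEIVER_GAIN", "OFFSET_FREQUENCY",
                 "CHEMICAL_SHIFT_REF_CPD", "TEMPERATURE", "NUMBER_OF_SCANS",
                 "DUMMY_SCANS", "ACQUISITION_TIME", "RELAXATION_DELAY",
                 "SPECTRAL_WIDTH", "NUM_DATA_POINTS_ACQUIRED", "REAL_DATA_POINTS",
                 "LINE_BROADENING", "ZERO_FILLING", "APODIZATION",
                 "BASELINE_CORRECTION_METHOD", "CHEMICAL_SHIFT_REF_STD", "BINNED_INCREMENT",
                 "BINNED_DATA_NORMALIZATION_METHOD", "BINNED_DATA_PROTOCOL_FILE",
                 "BINNED_DATA_CHEMICAL_SHIFT_RANGE", "BINNED_DATA_EXCLUDED_RANGE"]
  }
}
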