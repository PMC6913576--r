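TABLE_CD,COLUMN_CD,LOCAL_IN_CD,FHIR_OUT_CD,FHIR_SYSTEM
VISIT_DIMENSION,INOUT_CD,EMERGENCY,EMER,https://hl7.org/fhir/STU3/v3/ActEncounterCode/vs.html
VISIT_DIMENSION,INOUT_CD,INPATIENT,IMP,https://hl7.org/fhir/STU3/v3/ActEncounterCode/vs.html
VISIT_DIMENSION,INOUT_CD,OUTPATIENT,AMB,https://hl7.org/fhir/STU3/v3/ActEncounterCode/vs.html
PATIENT_DIMENSION,SEX_CD,MALE,male,http://hl7.org/fhir/administrative-gender
PATIENT_DIMENSION,SEX_CD,FEMALE,female,http://hl7.org/fhir/administrative-gender
PATIENT_DIMENSION,RACE_CD,WHITE,2106-3,urn:oid:2.16.840.1.113883.6.238
PATIENT_DIMENSION,RACE_CD,BLACK,2054-5,urn:oid:2.16.840.1.113883.6.238
PATIENT_DIMENSION,RACE_CD,ASIAN,2028-9,urn:oid:2.16.840.1.113883.6.238
PATIENT_DIMENSION,RACE_CD,AMERICAN-INDIAN,1002-5,urn:oid:2.16.840.1.113883.6.238
PATIENT_DIMENSION,RACE_CD,PACIFIC-ISLANDER,2076-8,urn:oid:2.16.840.1.113883.6.238
PATIENT_DIMENSION,ETHNICITY_CD,HISPANIC,2135-2,urn:oid:2.16.840.1.113883.6.238
PATIENT_DIMENSION,ETHNICITY_CD,NOT-HISPANIC,2186-5,urn:oid:2.16.840.1.113883.6.238
OBSERVATION_FACT,SMOKING_CD,CURRENT-SMOKER,449868002,http://snomed.info/sct
OBSERVATION_FACT,SMOKING_CD,FORMER-SMOKER,8517006,http://snomed.info/sct
OBSERVATION_FACT,SMOKING_CD,NEVER-SMOKER,266919005,http://snomed.info/sct
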