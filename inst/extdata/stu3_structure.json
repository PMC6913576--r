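{
  "comment": "Structural-definition snapshot of the FHIR STU3 (3.0.1) shapes for the seven supported resource types, transcribed from the published resource definitions. Element lists cover the full set of elements this profile admits; unknown elements are rejected.",
  "types": {
    "Coding": {
      "elements": {
        "system": {"type": "uri"},
        "version": {"type": "string"},
        "code": {"type": "code"},
        "display": {"type": "string"},
        "userSelected": {"type": "boolean"}
      }
    },
    "CodeableConcept": {
      "elements": {
        "coding": {"type": "Coding", "array": true},
        "text": {"type": "string"}
      }
    },
    "Quantity": {
      "elements": {
        "value": {"type": "decimal"},
        "comparator": {"type": "code", "enum": ["<", "<=", ">=", ">"]},
        "unit": {"type": "string"},
        "system": {"type": "uri"},
        "code": {"type": "code"}
      }
    },
    "Reference": {
      "elements": {
        "reference": {"type": "reference-string"},
        "display": {"type": "string"}
      }
    },
    "Identifier": {
      "elements": {
        "use": {"type": "code"},
        "system": {"type": "uri"},
        "value": {"type": "string"}
      }
    },
    "Period": {
      "elements": {
        "start": {"type": "dateTime"},
        "end": {"type": "dateTime"}
      }
    },
    "HumanName": {
      "elements": {
        "use": {"type": "code"},
        "text": {"type": "string"},
        "family": {"type": "string"},
        "given": {"type": "string", "array": true}
      }
    },
    "Extension": {
      "elements": {
        "url": {"type": "uri"},
        "extension": {"type": "Extension", "array": true},
        "valueCoding": {"type": "Coding"},
        "valueString": {"type": "string"},
        "valueCode": {"type": "code"}
      }
    },
    "Observation.referenceRange": {
      "elements": {
        "low": {"type": "Quantity"},
        "high": {"type": "Quantity"},
        "text": {"type": "string"}
      }
    },
    "Encounter.hospitalization": {
      "elements": {
        "admitSource": {"type": "CodeableConcept"},
        "dischargeDisposition": {"type": "CodeableConcept"}
      }
    }
  },
  "resources": {
    "Patient": {
      "elements": {
        "id": {"type": "id"},
        "identifier": {"type": "Identifier", "array": true},
        "extension": {"type": "Extension", "array": true},
        "active": {"type": "boolean"},
        "name": {"type": "HumanName", "array": true},
        "gender": {"type": "code", "enum": ["male", "female", "other", "unknown"]},
        "birthDate": {"type": "date"},
        "deceasedBoolean": {"type": "boolean"},
        "deceasedDateTime": {"type": "dateTime"}
      }
    },
    "Encounter": {
      "elements": {
        "id": {"type": "id"},
        "identifier": {"type": "Identifier", "array": true},
        "status": {"type": "code", "required": true, "enum": ["planned", "arrived", "triaged", "in-progress", "onleave", "finished", "cancelled", "entered-in-error", "unknown"]},
        "class": {"type": "Coding"},
        "type": {"type": "CodeableConcept", "array": true},
        "subject": {"type": "Reference"},
        "period": {"type": "Period"},
        "hospitalization": {"type": "Encounter.hospitalization"}
      }
    },
    "Condition": {
      "elements": {
        "id": {"type": "id"},
        "identifier": {"type": "Identifier", "array": true},
        "clinicalStatus": {"type": "code"},
        "verificationStatus": {"type": "code"},
        "code": {"type": "CodeableConcept"},
        "subject": {"type": "Reference", "required": true},
        "context": {"type": "Reference"},
        "onsetDateTime": {"type": "dateTime"},
        "assertedDate": {"type": "dateTime"}
      }
    },
    "Procedure": {
      "elements": {
        "id": {"type": "id"},
        "identifier": {"type": "Identifier", "array": true},
        "status": {"type": "code", "required": true, "enum": ["preparation", "in-progress", "suspended", "aborted", "completed", "entered-in-error", "unknown"]},
        "code": {"type": "CodeableConcept"},
        "subject": {"type": "Reference", "required": true},
        "context": {"type": "Reference"},
        "performedDateTime": {"type": "dateTime"}
      }
    },
    "Observation": {
      "elements": {
        "id": {"type": "id"},
        "identifier": {"type": "Identifier", "array": true},
        "status": {"type": "code", "required": true, "enum": ["registered", "preliminary", "final", "amended", "corrected", "cancelled", "entered-in-error", "unknown"]},
        "category": {"type": "CodeableConcept", "array": true},
        "code": {"type": "CodeableConcept", "required": true},
        "subject": {"type": "Reference"},
        "context": {"type": "Reference"},
        "effectiveDateTime": {"type": "dateTime"},
        "issued": {"type": "instant"},
        "valueQuantity": {"type": "Quantity"},
        "valueString": {"type": "string"},
        "valueCodeableConcept": {"type": "CodeableConcept"},
        "interpretation": {"type": "CodeableConcept"},
        "referenceRange": {"type": "Observation.referenceRange", "array": true}
      }
    },
    "MedicationRequest": {
      "elements": {
        "id": {"type": "id"},
        "identifier": {"type": "Identifier", "array": true},
        "status": {"type": "code", "enum": ["active", "on-hold", "cancelled", "completed", "entered-in-error", "stopped", "draft", "unknown"]},
        "intent": {"type": "code", "required": true, "enum": ["proposal", "plan", "order", "instance-order"]},
        "medicationCodeableConcept": {"type": "CodeableConcept", "required": true},
        "subject": {"type": "Reference"},
        "context": {"type": "Reference"},
        "authoredOn": {"type": "dateTime"}
      }
    },
    "Practitioner": {
      "elements": {
        "id": {"type": "id"},
        "identifier": {"type": "Identifier", "array": true},
        "active": {"type": "boolean"},
        "name": {"type": "HumanName", "array": true},
        "gender": {"type": "code", "enum": ["male", "female", "other", "unknown"]}
      }
    }
  }
}
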